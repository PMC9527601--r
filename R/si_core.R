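# GSI transmission model: gamete distributions with recombination, pollen
# acceptance under non-self recognition, cross classification and offspring
# prediction.
#
# Model assumptions (documented in the methods vignette):
#   * diploid meiosis: for haplotypes h1, h2 and a linked locus with fraction r,
#     parental gametes each (1 - r)/2 and recombinants each r/2; several linked
#     loci recombine independently (no interference);
#   * tetraploid meiosis: random bivalent pairing, no double reduction, each
#     bivalent recombining as a diploid; marginally all 6 unordered haplotype
#     pairs are equiprobable;
#   * haploid pollen is rejected iff its S-allele matches either pistil
#     S-allele (anonymous alleles never match); heteroallelic diploid pollen is
#     unconditionally accepted (non-self-recognition breakdown after
#     polyploidization).

# ---- gamete distribution ----------------------------------------------------

# gametes from one pair of haplotypes (a bivalent), as list(haps=list, prob)
.bivalent_gametes <- function(h1, h2, rmap) {
  loci <- sort(names(h1$traits))
  out <- list()
  origins <- if (length(loci)) {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(loci))))
  } else {
    matrix(FALSE, nrow = 1, ncol = 0)
  }
  pair <- list(h1, h2)
  for (sidx in 1:2) {
    own <- pair[[sidx]]
    other <- pair[[3L - sidx]]
    for (k in seq_len(nrow(origins))) {
      recomb <- origins[k, ]
      p <- 0.5
      traits <- character(length(loci))
      names(traits) <- loci
      for (j in seq_along(loci)) {
        r <- .r_for(rmap, loci[j])
        if (recomb[j]) {
          traits[j] <- other$traits[[loci[j]]]
          p <- p * r
        } else {
          traits[j] <- own$traits[[loci[j]]]
          p <- p * (1 - r)
        }
      }
      g <- structure(list(s = own$s, anonymous = own$anonymous, traits = traits),
                     class = "haplotype")
      out[[length(out) + 1L]] <- list(hap = g, prob = p)
    }
  }
  # merge identical gametes (alleles may coincide across haplotypes)
  keys <- vapply(out, function(x) .hap_key(x$hap), character(1))
  probs <- vapply(out, function(x) x$prob, numeric(1))
  agg <- tapply(probs, keys, sum)
  agg <- agg[agg > 0]  # r = 0 must yield parental classes only
  lapply(names(agg), function(k) {
    list(hap = out[[match(k, keys)]]$hap, prob = unname(agg[[k]]))
  })
}

#' Pollen/ovule gamete distribution of a parent
#'
#' Enumerates the gamete classes of a diploid or tetraploid parent under the
#' recombination map. Diploid parents yield haploid gametes; tetraploid parents
#' yield diploid gametes via random bivalent pairing without double reduction.
#' Triploids are not supported (aneuploid gametes are not modelled).
#'
#' @param parent a [plant_genotype()] of ploidy 2 or 4.
#' @param rmap a [recomb_map()] (or named numeric); missing loci are unlinked.
#' @return a list of pollen classes, each `list(haplotypes = <list>, prob = <num>)`,
#'   with probabilities summing to 1.
#' @examples
#' p <- plant_genotype("P", haplotype("S1", KSN = "ksn_null"),
#'                          haplotype("S3", KSN = "KSN_W"))
#' gamete_distribution(p, recomb_map(KSN = 0.2))
#' @export
gamete_distribution <- function(parent, rmap = NULL) {
  stopifnot(inherits(parent, "plant_genotype"))
  if (!is.null(rmap)) .check_r(unclass(rmap))
  if (parent$ploidy == 3L) {
    stop("triploid parents are not supported: aneuploid gametes are not modelled")
  }
  if (parent$ploidy == 2L) {
    g <- .bivalent_gametes(parent$haplotypes[[1]], parent$haplotypes[[2]], rmap)
    return(lapply(g, function(x) list(haplotypes = list(x$hap), prob = x$prob)))
  }
  # tetraploid: three bivalent pairings, each 1/3
  pairings <- list(list(c(1L, 2L), c(3L, 4L)),
                   list(c(1L, 3L), c(2L, 4L)),
                   list(c(1L, 4L), c(2L, 3L)))
  acc <- list()
  for (pr in pairings) {
    gA <- .bivalent_gametes(parent$haplotypes[[pr[[1]][1]]],
                            parent$haplotypes[[pr[[1]][2]]], rmap)
    gB <- .bivalent_gametes(parent$haplotypes[[pr[[2]][1]]],
                            parent$haplotypes[[pr[[2]][2]]], rmap)
    for (a in gA) for (b in gB) {
      acc[[length(acc) + 1L]] <- list(haplotypes = list(a$hap, b$hap),
                                      prob = a$prob * b$prob / 3)
    }
  }
  .merge_classes(acc)
}

# merge classes with identical (unordered) haplotype sets
.merge_classes <- function(classes) {
  keys <- vapply(classes, function(cl) {
    paste(sort(vapply(cl$haplotypes, .hap_key, character(1))), collapse = " / ")
  }, character(1))
  probs <- vapply(classes, function(cl) cl$prob, numeric(1))
  agg <- tapply(probs, keys, sum)
  agg <- agg[agg > 0]
  out <- lapply(names(agg), function(k) {
    cl <- classes[[match(k, keys)]]
    list(haplotypes = cl$haplotypes, prob = unname(agg[[k]]))
  })
  out[order(names(agg))]
}

# ---- acceptance -------------------------------------------------------------

.s_match <- function(a, b) {
  # anonymous alleles never match anything, including each other
  identical(a$s, b$s) && !a$anonymous && !b$anonymous
}

#' GSI pollen acceptance by a pistil
#'
#' Haploid pollen is rejected iff its S-allele matches either S-allele of the
#' pistil; anonymous alleles never match. Diploid pollen carrying two distinct
#' S-alleles is accepted unconditionally (the non-self-recognition breakdown
#' that makes chromosome-doubled tetraploids self-compatible); homoallelic
#' diploid pollen follows the haploid rule.
#'
#' @param pollen a pollen class from [gamete_distribution()], or a list of 1-2
#'   [haplotype()] objects.
#' @param pistil the pistil parent, a [plant_genotype()].
#' @return `TRUE` if the pollen is accepted.
#' @export
pollen_accepted <- function(pollen, pistil) {
  stopifnot(inherits(pistil, "plant_genotype"))
  haps <- if (!is.null(pollen$haplotypes)) pollen$haplotypes else pollen
  if (inherits(haps, "haplotype")) haps <- list(haps)
  if (!length(haps) %in% 1:2) stop("pollen must carry 1 or 2 haplotypes")
  if (length(haps) == 2L && !identical(haps[[1]]$s, haps[[2]]$s)) {
    return(TRUE)  # heteroallelic diploid pollen: competitive interaction
  }
  grain <- haps[[1]]
  !any(vapply(pistil$haplotypes, function(ph) .s_match(grain, ph), logical(1)))
}

# ---- cross ------------------------------------------------------------------

#' Predict a controlled cross under GSI
#'
#' Forms the pollen gamete distribution of the pollen parent, filters it by
#' pistil acceptance, renormalizes, and combines it with the unselected ovule
#' distribution of the seed parent into an offspring genotype distribution.
#'
#' @param seed_parent diploid [plant_genotype()] (pistil side).
#' @param pollen_parent diploid or tetraploid [plant_genotype()].
#' @param rmap optional [recomb_map()].
#' @return an object of class `"gsi_cross"` with elements `compatibility`
#'   (`"INCOMPATIBLE"`, `"HALF_COMPATIBLE"` or `"FULLY_COMPATIBLE"`),
#'   `accepted_fraction`, `pollen` (post-acceptance classes), and `offspring`
#'   (list of `list(haplotypes, prob)`; empty when incompatible).
#' @examples
#' m <- plant_genotype("M", haplotype("S_x"), haplotype("S_C1"))
#' f <- plant_genotype("F", haplotype("S_C1"), haplotype("S_y"))
#' cross(m, f)
#' @export
cross <- function(seed_parent, pollen_parent, rmap = NULL) {
  stopifnot(inherits(seed_parent, "plant_genotype"),
            inherits(pollen_parent, "plant_genotype"))
  if (seed_parent$ploidy != 2L) stop("seed parent must be diploid")
  if (!pollen_parent$ploidy %in% c(2L, 4L)) {
    stop("pollen parent must be diploid or tetraploid")
  }
  pollen <- gamete_distribution(pollen_parent, rmap)
  ok <- vapply(pollen, pollen_accepted, logical(1), pistil = seed_parent)
  accepted_fraction <- sum(vapply(pollen[ok], `[[`, numeric(1), "prob"))
  tol <- 1e-12
  compatibility <- if (accepted_fraction <= tol) {
    "INCOMPATIBLE"
  } else if (accepted_fraction >= 1 - tol) {
    "FULLY_COMPATIBLE"
  } else {
    "HALF_COMPATIBLE"
  }
  accepted <- pollen[ok]
  offspring <- list()
  if (accepted_fraction > tol) {
    accepted <- lapply(accepted, function(cl) {
      cl$prob <- cl$prob / accepted_fraction
      cl
    })
    ovules <- gamete_distribution(seed_parent, rmap)
    for (ov in ovules) for (po in accepted) {
      offspring[[length(offspring) + 1L]] <-
        list(haplotypes = c(ov$haplotypes, po$haplotypes),
             prob = ov$prob * po$prob)
    }
    offspring <- .merge_classes(offspring)
  } else {
    accepted <- list()
  }
  structure(list(seed_parent = seed_parent, pollen_parent = pollen_parent,
                 rmap = rmap, compatibility = compatibility,
                 accepted_fraction = accepted_fraction,
                 pollen = accepted, offspring = offspring),
            class = "gsi_cross")
}

#' Offspring S-genotype distribution of a cross
#'
#' Collapses the full offspring genotype distribution onto unordered S-allele
#' sets, keyed like `"S_C1/S_y"` (labels sorted within a genotype).
#'
#' @param x a `"gsi_cross"` object.
#' @return named numeric vector of probabilities (empty when incompatible).
#' @export
s_genotype_distribution <- function(x) {
  stopifnot(inherits(x, "gsi_cross"))
  if (!length(x$offspring)) return(numeric(0))
  keys <- vapply(x$offspring, function(o) {
    paste(sort(vapply(o$haplotypes, function(h) h$s, character(1))), collapse = "/")
  }, character(1))
  probs <- vapply(x$offspring, `[[`, numeric(1), "prob")
  agg <- tapply(probs, keys, sum)
  stats::setNames(as.numeric(agg), names(agg))
}

#' @export
print.gsi_cross <- function(x, ...) {
  cat("<gsi_cross> ", x$seed_parent$id, " (seed) x ", x$pollen_parent$id,
      " (pollen)\n", sep = "")
  cat("  compatibility:    ", x$compatibility, "\n", sep = "")
  cat("  accepted pollen:  ", format(x$accepted_fraction), "\n", sep = "")
  sg <- s_genotype_distribution(x)
  if (length(sg)) {
    cat("  offspring S-genotypes:\n")
    for (k in names(sg)) cat(sprintf("    %-20s %.4f\n", k, sg[[k]]))
  } else {
    cat("  no offspring (incompatible cross)\n")
  }
  invisible(x)
}

#' @export
summary.gsi_cross <- function(object, ...) {
  print(object)
  if (length(object$offspring)) {
    cat("  full genotype classes: ", length(object$offspring), "\n", sep = "")
  }
  invisible(object)
}

# ---- trait predictions ------------------------------------------------------

#' Predicate: all alleles at a locus are non-functional
#'
#' The continuous-flowering (CF) phenotype, for example, requires every KSN
#' allele of a genotype to be non-functional (`ksn_copia`/`ksn_null`).
#'
#' @param alleles character vector of allele labels at one locus.
#' @param locus the locus name (used for the functionality lookup).
#' @return logical.
#' @export
predicate_all_nonfunctional <- function(alleles, locus) {
  fun <- vapply(alleles, function(a) trait_functional(locus, a), logical(1))
  if (anyNA(fun)) {
    stop("unregistered allele(s) at locus '", locus, "': ",
         paste(alleles[is.na(fun)], collapse = ", "),
         "; see register_trait_allele()", call. = FALSE)
  }
  !any(fun)
}

#' Expected fraction of offspring satisfying a trait predicate
#'
#' Sums offspring probabilities over genotypes whose alleles at `locus` satisfy
#' `predicate`. With the default predicate this is the expected fraction of
#' offspring whose alleles at the locus are all non-functional — e.g. the
#' expected CF fraction at `locus = "KSN"`.
#'
#' @param result a `"gsi_cross"` object with offspring.
#' @param locus trait locus name present in the haplotypes.
#' @param predicate `function(alleles, locus) -> logical`.
#' @return a probability in `[0, 1]`.
#' @examples
#' m <- plant_genotype("M", haplotype("S1", KSN = "ksn_null"),
#'                          haplotype("S2", KSN = "ksn_null"))
#' f <- plant_genotype("F", haplotype("S1", KSN = "ksn_null"),
#'                          haplotype("S3", KSN = "KSN_W"))
#' expected_trait_fraction(cross(m, f, recomb_map(KSN = 0.2)), "KSN")
#' @export
expected_trait_fraction <- function(result, locus,
                                    predicate = predicate_all_nonfunctional) {
  stopifnot(inherits(result, "gsi_cross"))
  if (!length(result$offspring)) {
    stop("cross has no offspring distribution (incompatible cross?)")
  }
  total <- 0
  for (o in result$offspring) {
    alleles <- vapply(o$haplotypes, .allele_at, character(1), locus = locus)
    if (isTRUE(predicate(alleles, locus))) total <- total + o$prob
  }
  total
}
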