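# Inference from observed segregation data: pollen-genotype inference from
# seeds, tests against GSI expectations, recombination-fraction estimation,
# co-segregation checks, and cM -> bp regression positioning.

# ---- seed genotype counts ---------------------------------------------------

#' Seed genotype count table for one cross
#'
#' Mirrors a pollination-experiment table row set: the maternal genotype plus
#' counts of seeds per offspring S-genotype (unordered, `"A/B"`-keyed).
#'
#' @param cross_id identifier of the cross.
#' @param maternal diploid [plant_genotype()] of the seed parent.
#' @param counts data.frame with columns `seed_genotype` (strings like
#'   `"S_x/S_y"`) and `count` (non-negative integers), or a named numeric
#'   vector keyed by genotype.
#' @return an object of class `"seed_genotype_counts"`.
#' @export
seed_genotype_counts <- function(cross_id, maternal, counts) {
  stopifnot(inherits(maternal, "plant_genotype"), maternal$ploidy == 2L)
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- data.frame(seed_genotype = names(counts), count = as.numeric(counts))
  }
  stopifnot(is.data.frame(counts),
            all(c("seed_genotype", "count") %in% names(counts)))
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("counts must be non-negative integers")
  }
  structure(list(cross_id = as.character(cross_id), maternal = maternal,
                 counts = counts[, c("seed_genotype", "count")]),
            class = "seed_genotype_counts")
}

#' Split a genotype string into allele labels
#' @param genotype strings like `"S_C1/S_y"`.
#' @return list of character vectors.
#' @export
parse_genotype <- function(genotype) {
  strsplit(as.character(genotype), "/", fixed = TRUE)
}

# ---- pollen inference -------------------------------------------------------

#' Infer the pollen-derived S-allele of a seed
#'
#' Removes one maternal allele from the seed genotype; the remainder is the
#' pollen allele. Returns status `"AMBIGUOUS"` when two different removals are
#' possible and `"INCONSISTENT"` when the seed carries no maternal allele.
#' Matching is by exact label (anonymous labels act as ordinary per-cross
#' bookkeeping labels here; anonymity matters only to SI recognition).
#'
#' @param seed character vector of the seed's S-alleles (length 2 for diploid
#'   seeds), or a `"A/B"` genotype string.
#' @param maternal diploid [plant_genotype()] or character vector of two
#'   maternal alleles.
#' @return `list(status = "OK"|"AMBIGUOUS"|"INCONSISTENT", allele = <chr or NA>)`.
#' @examples
#' infer_pollen_allele(c("S_21", "S_C1"), c("S_21", "S_C2"))
#' @export
infer_pollen_allele <- function(seed, maternal) {
  if (length(seed) == 1L && grepl("/", seed)) seed <- parse_genotype(seed)[[1]]
  if (inherits(maternal, "plant_genotype")) {
    stopifnot(maternal$ploidy == 2L)
    maternal <- s_alleles(maternal)
  }
  stopifnot(is.character(seed), length(seed) == 2L,
            is.character(maternal), length(maternal) == 2L)
  candidates <- character(0)
  # remove each maternal allele present in the seed; remainder = pollen allele
  for (m in unique(maternal)) {
    i <- match(m, seed)
    if (!is.na(i)) candidates <- c(candidates, seed[-i])
  }
  candidates <- unique(candidates)
  if (!length(candidates)) {
    list(status = "INCONSISTENT", allele = NA_character_)
  } else if (length(candidates) > 1L) {
    list(status = "AMBIGUOUS", allele = NA_character_)
  } else {
    list(status = "OK", allele = candidates)
  }
}

#' Test pollen transmission of a shared S-allele against the no-SI null
#'
#' For a half-compatible cross, tallies how many seeds derive from pollen
#' carrying the shared allele versus any other allele, and tests the tally
#' against equal transmission (binomial, p = 0.5) — the expectation if the
#' shared allele's pollen were not rejected. Ambiguous or inconsistent seeds
#' are excluded and reported.
#'
#' @param counts a [seed_genotype_counts()] object.
#' @param shared_allele label of the S-allele shared by the two parents.
#' @return object of class `"pollen_ratio_test"`: `n_shared`, `n_other`,
#'   `total`, `expected_under_no_SI`, `p_value`, `n_ambiguous`,
#'   `n_inconsistent`.
#' @export
pollen_ratio_test <- function(counts, shared_allele) {
  stopifnot(inherits(counts, "seed_genotype_counts"),
            is.character(shared_allele), length(shared_allele) == 1L)
  n_shared <- n_other <- n_amb <- n_inc <- 0
  for (i in seq_len(nrow(counts$counts))) {
    n <- counts$counts$count[i]
    if (n == 0) next
    inf <- infer_pollen_allele(counts$counts$seed_genotype[i], counts$maternal)
    if (inf$status == "AMBIGUOUS") {
      n_amb <- n_amb + n
    } else if (inf$status == "INCONSISTENT") {
      n_inc <- n_inc + n
    } else if (identical(inf$allele, shared_allele)) {
      n_shared <- n_shared + n
    } else {
      n_other <- n_other + n
    }
  }
  total <- n_shared + n_other
  p <- if (total > 0) {
    stats::binom.test(n_shared, total, p = 0.5)$p.value
  } else {
    NA_real_
  }
  structure(list(cross_id = counts$cross_id, shared_allele = shared_allele,
                 n_shared = n_shared, n_other = n_other, total = total,
                 expected_under_no_SI = total / 2, p_value = p,
                 n_ambiguous = n_amb, n_inconsistent = n_inc),
            class = "pollen_ratio_test")
}

#' @export
print.pollen_ratio_test <- function(x, ...) {
  cat("<pollen_ratio_test> cross ", x$cross_id, ", shared allele ",
      x$shared_allele, "\n", sep = "")
  cat(sprintf("  pollen-derived %s: %d of %d seeds (expected %.1f under no SI)\n",
              x$shared_allele, x$n_shared, x$total, x$expected_under_no_SI))
  cat(sprintf("  exact binomial p = %.3g\n", x$p_value))
  if (x$n_ambiguous + x$n_inconsistent > 0) {
    cat(sprintf("  excluded: %d ambiguous, %d inconsistent\n",
                x$n_ambiguous, x$n_inconsistent))
  }
  invisible(x)
}

# ---- F1 tables and recombination --------------------------------------------

#' Phased F1 genotype table
#'
#' Holds per-gamete transmitted alleles: one row per (individual, parent), one
#' column per locus (`"S"` plus trait loci), entries being the allele labels the
#' gamete carried (NA = missing call). Parental phases are carried alongside.
#'
#' @param gametes data.frame with columns `individual`, `parent` and one column
#'   per locus.
#' @param parents named list of [plant_genotype()] objects; names must cover
#'   the values of `gametes$parent`.
#' @return an object of class `"f1_genotype_table"`.
#' @export
f1_genotype_table <- function(gametes, parents) {
  stopifnot(is.data.frame(gametes), nrow(gametes) > 0,
            all(c("individual", "parent") %in% names(gametes)),
            is.list(parents), !is.null(names(parents)))
  if (!all(unique(gametes$parent) %in% names(parents))) {
    stop("every gametes$parent value must name an entry of `parents`")
  }
  structure(list(gametes = gametes, parents = parents),
            class = "f1_genotype_table")
}

.parental_pairs <- function(parent, locusA, locusB) {
  vapply(parent$haplotypes, function(h) {
    paste(.allele_at(h, locusA), .allele_at(h, locusB), sep = "\r")
  }, character(1))
}

# informative gamete rows for one parent at two loci; errors on non-parental calls
.scored_gametes <- function(table, locusA, locusB, parent) {
  stopifnot(inherits(table, "f1_genotype_table"))
  if (!all(c(locusA, locusB) %in% names(table$gametes))) {
    stop("loci '", locusA, "'/'", locusB, "' not present in the F1 table")
  }
  rows <- table$gametes[table$gametes$parent == parent, , drop = FALSE]
  if (!nrow(rows)) stop("no gametes scored for parent '", parent, "'")
  keep <- !is.na(rows[[locusA]]) & !is.na(rows[[locusB]])
  rows <- rows[keep, , drop = FALSE]
  if (!nrow(rows)) stop("insufficient data: no complete calls at both loci")
  pg <- table$parents[[parent]]
  for (loc in c(locusA, locusB)) {
    ok <- rows[[loc]] %in% vapply(pg$haplotypes, .allele_at, character(1), locus = loc)
    if (!all(ok)) {
      stop("non-parental allele call(s) at locus '", loc, "' for parent '",
           parent, "'")
    }
  }
  rows
}

#' Estimate the recombination fraction between two loci
#'
#' Counts gametes of the informative parent whose two-locus allele combination
#' is non-parental; `r_hat = recombinants / total`. The percent presentation
#' rounds half away from zero to an integer.
#'
#' @param table an [f1_genotype_table()].
#' @param locusA,locusB locus names (e.g. `"S"`, `"KSN"`).
#' @param parent name of the informative parent in `table$parents`.
#' @return object of class `"recomb_estimate"`: `recombinants`, `total`,
#'   `r_hat`, `percent`.
#' @export
estimate_recombination <- function(table, locusA, locusB, parent) {
  rows <- .scored_gametes(table, locusA, locusB, parent)
  parental <- .parental_pairs(table$parents[[parent]], locusA, locusB)
  observed <- paste(rows[[locusA]], rows[[locusB]], sep = "\r")
  rec <- sum(!observed %in% parental)
  total <- nrow(rows)
  structure(list(locusA = locusA, locusB = locusB, parent = parent,
                 recombinants = rec, total = total, r_hat = rec / total,
                 percent = round_half_up(100 * rec / total)),
            class = "recomb_estimate")
}

#' @export
print.recomb_estimate <- function(x, ...) {
  cat(sprintf("<recomb_estimate> %s - %s (parent %s): %d / %d recombinants, r = %.3f (%d%%)\n",
              x$locusA, x$locusB, x$parent, x$recombinants, x$total, x$r_hat,
              as.integer(x$percent)))
  invisible(x)
}

#' Test two loci for perfect co-segregation
#'
#' @inheritParams estimate_recombination
#' @return `list(n, n_discordant, perfectly_cosegregating)`.
#' @export
cosegregation_test <- function(table, locusA, locusB, parent) {
  est <- estimate_recombination(table, locusA, locusB, parent)
  list(n = est$total, n_discordant = est$recombinants,
       perfectly_cosegregating = est$recombinants == 0L)
}

# ---- map position regression ------------------------------------------------

#' Estimate a physical position from a genetic map position
#'
#' Fits an ordinary least-squares line bp ~ cM on the `k_flank` markers nearest
#' to the target on each side (fewer at map ends) and predicts the physical
#' coordinate at `target_cm`.
#'
#' @param markers data.frame with columns `name`, `cm` (centiMorgan) and `bp`
#'   (1-based physical coordinate).
#' @param target_cm map position to place.
#' @param k_flank markers used per side (default 3).
#' @return `list(bp, slope, intercept, markers_used, monotone)`; a warning is
#'   raised when cM and bp are not monotone among the chosen markers.
#' @examples
#' m <- data.frame(name = c("a", "b"), cm = c(10, 20), bp = c(1e6, 2e6))
#' estimate_physical_position(m, 15)
#' @export
estimate_physical_position <- function(markers, target_cm, k_flank = 3L) {
  stopifnot(is.data.frame(markers), all(c("cm", "bp") %in% names(markers)),
            is.numeric(target_cm), length(target_cm) == 1L, k_flank >= 1L)
  usable <- markers[is.finite(markers$cm) & is.finite(markers$bp), , drop = FALSE]
  if (nrow(usable) < 2L) stop("insufficient data: need >= 2 usable markers")
  # deterministic ordering so permuting the input never changes the choice
  ord <- order(usable$cm, usable$bp, as.character(usable$name))
  usable <- usable[ord, , drop = FALSE]
  below <- which(usable$cm <= target_cm)
  above <- which(usable$cm > target_cm)
  pick_below <- utils::tail(below, k_flank)
  pick_above <- utils::head(above, k_flank)
  chosen <- usable[c(pick_below, pick_above), , drop = FALSE]
  if (nrow(chosen) < 2L) stop("insufficient data: fewer than 2 flanking markers")
  fit <- stats::lm(bp ~ cm, data = chosen)
  d <- diff(chosen$bp[order(chosen$cm)])
  monotone <- all(d >= 0) || all(d <= 0)
  if (!monotone) {
    warning("cM vs bp not monotone among the chosen flanking markers")
  }
  list(bp = unname(stats::predict(fit, data.frame(cm = target_cm))),
       slope = unname(stats::coef(fit)[["cm"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       markers_used = chosen, monotone = monotone)
}
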