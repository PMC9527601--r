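# Shared builders for test fixtures (all generated in code; no binary data).

# the half-compatible pair validated by the pollination experiments
half_compatible_pair <- function() {
  list(mother = plant_genotype("M", haplotype("S_x"), haplotype("S_C1")),
       father = plant_genotype("F", haplotype("S_C1"), haplotype("S_y")))
}

# CF seed parent (ksn/ksn) x half-compatible pollen donor carrying one KSN_W
cf_breeding_cross <- function(r = 0.2) {
  list(mother = plant_genotype("CFm", haplotype("S1", KSN = "ksn_null"),
                                       haplotype("S2", KSN = "ksn_null")),
       father = plant_genotype("Dn", haplotype("S1", KSN = "ksn_null"),
                                      haplotype("S3", KSN = "KSN_W")),
       rmap = recomb_map(KSN = r))
}

# random diploid plant over `loci`, alleles drawn from a small pool
random_diploid <- function(id, loci, allele_pool = paste0("S", 1:6)) {
  s <- sample(allele_pool, 2)
  haps <- lapply(1:2, function(i) {
    traits <- stats::setNames(
      sapply(loci, function(l) paste0(l, "_a", sample(2, 1))), loci)
    do.call(haplotype, c(list(s = s[i]), as.list(traits)))
  })
  plant_genotype(id, haps)
}

# phased F1 gamete table with an exact recombinant count at two loci
f1_with_counts <- function(parent, locusA, locusB, n_recomb, n_total,
                           other_parent = NULL) {
  h <- parent$haplotypes
  a <- vapply(h, function(x) if (locusA == "S") x$s else x$traits[[locusA]],
              character(1))
  b <- vapply(h, function(x) if (locusB == "S") x$s else x$traits[[locusB]],
              character(1))
  la <- c(rep(a[1], n_total - n_recomb), rep(a[1], n_recomb))
  lb <- c(rep(b[1], n_total - n_recomb), rep(b[2], n_recomb))
  gametes <- data.frame(individual = seq_len(n_total), parent = parent$id)
  gametes[[locusA]] <- la
  gametes[[locusB]] <- lb
  parents <- stats::setNames(list(parent), parent$id)
  if (!is.null(other_parent)) parents[[other_parent$id]] <- other_parent
  f1_genotype_table(gametes, parents)
}

# parents of the FW-style mapping population (phased at S, KSN, AP2)
mapping_parents <- function() {
  list(
    TF = plant_genotype("TF",
      haplotype("S_C2", KSN = "ksn_null", AP2 = "ap2"),
      haplotype("S_21", KSN = "KSN_W", AP2 = "AP2_W")),
    RW = plant_genotype("RW",
      haplotype("S_1w", KSN = "ksn_copia", AP2 = "ap2"),
      haplotype("S_x2", KSN = "KSN_W", AP2 = "AP2_W"))
  )
}

extdata <- function(...) {
  p <- system.file("extdata", ..., package = "gsicross")
  if (nzchar(p)) p else file.path("../../inst/extdata", ...)
}

# independent brute-force oracle for a diploid x diploid cross:
# enumerates ovule x pollen haplotype pairs directly from the definition
oracle_cross_s_distribution <- function(mother, father, rmap = NULL) {
  gam <- function(p) {
    # direct (1-r)/2, r/2 enumeration; written independently of the package
    loci <- names(p$haplotypes[[1]]$traits)
    out <- list()
    for (si in 1:2) {
      origin_sets <- if (length(loci)) {
        expand.grid(rep(list(1:2), length(loci)))
      } else {
        data.frame(row.names = 1)
      }
      for (k in seq_len(nrow(origin_sets))) {
        pr <- 0.5
        traits <- character(0)
        for (j in seq_along(loci)) {
          src <- origin_sets[k, j]
          r <- if (!is.null(rmap) && loci[j] %in% names(rmap)) {
            unname(rmap[[loci[j]]])
          } else 0.5
          pr <- pr * if (src == si) (1 - r) else r
          traits[loci[j]] <- p$haplotypes[[src]]$traits[[loci[j]]]
        }
        out[[length(out) + 1L]] <- list(s = p$haplotypes[[si]]$s,
                                        anon = p$haplotypes[[si]]$anonymous,
                                        traits = traits, prob = pr)
      }
    }
    out
  }
  pol <- gam(father)
  pistil <- lapply(mother$haplotypes, function(h) list(s = h$s, anon = h$anonymous))
  acc <- Filter(function(g) {
    !any(vapply(pistil, function(ph) {
      identical(ph$s, g$s) && !ph$anon && !g$anon
    }, logical(1)))
  }, pol)
  af <- sum(vapply(acc, `[[`, numeric(1), "prob"))
  if (af == 0) return(list(accepted_fraction = 0, dist = numeric(0)))
  hapkey <- function(g) {
    if (!length(g$traits)) return(g$s)
    loci <- sort(names(g$traits))
    paste0(g$s, "|", paste(loci, g$traits[loci], sep = "=", collapse = ";"))
  }
  ov <- gam(mother)
  keys <- character(0); probs <- numeric(0)
  for (o in ov) for (q in acc) {
    key <- paste(sort(c(hapkey(o), hapkey(q))), collapse = " / ")
    i <- match(key, keys)
    p <- o$prob * q$prob / af
    if (is.na(i)) { keys <- c(keys, key); probs <- c(probs, p) }
    else probs[i] <- probs[i] + p
  }
  list(accepted_fraction = af, dist = stats::setNames(probs, keys))
}

# full-genotype key distribution of a gsi_cross result, matching the oracle's keys
cross_genotype_distribution <- function(cr) {
  keys <- vapply(cr$offspring, function(o) {
    paste(sort(vapply(o$haplotypes, function(h) {
      if (!length(h$traits)) return(h$s)
      loci <- sort(names(h$traits))
      paste0(h$s, "|", paste(loci, h$traits[loci], sep = "=", collapse = ";"))
    }, character(1))), collapse = " / ")
  }, character(1))
  stats::setNames(vapply(cr$offspring, `[[`, numeric(1), "prob"), keys)
}
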