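# Seeded generators producing inputs with the statistical structure the
# analyses assume: seed genotype sets from GSI-filtered crosses, phased F1
# tables with a set recombination fraction, cultivar marker panels with
# per-period carrier fractions, and sequence sets with a set divergence.
#
# Every generator takes an integer `seed` and sets the RNG, so a fixed seed
# reproduces the output exactly.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.DNA4 <- c("A", "C", "G", "T")

#' Simulate a seed genotype count table from a cross
#'
#' Draws `n` seeds from the offspring S-genotype distribution of
#' [cross()]`(seed_parent, pollen_parent, rmap)`. An incompatible cross yields
#' a zero-seed table carrying a notice.
#'
#' @param seed_parent,pollen_parent parents as [plant_genotype()].
#' @param n number of seeds.
#' @param seed RNG seed.
#' @param rmap optional [recomb_map()].
#' @param cross_id identifier for the output table.
#' @return a [seed_genotype_counts()] object.
#' @export
simulate_seed_set <- function(seed_parent, pollen_parent, n, seed,
                              rmap = NULL, cross_id = "sim") {
  set.seed(seed)
  cr <- cross(seed_parent, pollen_parent, rmap)
  if (cr$compatibility == "INCOMPATIBLE") {
    out <- seed_genotype_counts(cross_id, seed_parent,
                                data.frame(seed_genotype = character(0),
                                           count = integer(0)))
    attr(out, "notice") <- "incompatible cross: no seeds"
    return(out)
  }
  sg <- s_genotype_distribution(cr)
  draws <- sample(names(sg), n, replace = TRUE, prob = sg)
  tab <- table(factor(draws, levels = names(sg)))
  seed_genotype_counts(cross_id, seed_parent,
                       data.frame(seed_genotype = names(tab),
                                  count = as.integer(tab)))
}

#' Simulate a phased F1 genotype table
#'
#' Each individual receives one gamete from each parent, drawn from that
#' parent's [gamete_distribution()] (ovule side unselected; pollen selection is
#' not applied — mapping populations are made from compatible crosses).
#' Recombinant gametes therefore occur at rate r per meiosis per parent.
#'
#' @param mother,father diploid [plant_genotype()] parents.
#' @param n number of F1 individuals.
#' @param seed RNG seed.
#' @param rmap optional [recomb_map()].
#' @return an [f1_genotype_table()] with loci `"S"` plus the trait loci.
#' @export
simulate_f1 <- function(mother, father, n, seed, rmap = NULL) {
  set.seed(seed)
  stopifnot(mother$ploidy == 2L, father$ploidy == 2L)
  loci <- c("S", sort(names(mother$haplotypes[[1]]$traits)))
  draw <- function(parent) {
    g <- gamete_distribution(parent, rmap)
    idx <- sample(length(g), n, replace = TRUE,
                  prob = vapply(g, `[[`, numeric(1), "prob"))
    lapply(idx, function(i) g[[i]]$haplotypes[[1]])
  }
  gm <- draw(mother)
  gf <- draw(father)
  mk <- function(haps, parent_id) {
    df <- data.frame(individual = seq_len(n), parent = parent_id)
    for (loc in loci) {
      df[[loc]] <- vapply(haps, .allele_at, character(1), locus = loc)
    }
    df
  }
  gametes <- rbind(mk(gm, mother$id), mk(gf, father$id))
  f1_genotype_table(gametes, stats::setNames(list(mother, father),
                                             c(mother$id, father$id)))
}

#' Simulate a cultivar marker panel over breeding periods
#'
#' Bernoulli carrier draws per cultivar per marker group at the given
#' per-period fractions; a carrier gets one uniformly chosen marker of the
#' group set present. An optional linkage-hitchhiking parameter makes S_C
#' carriership conditional on ksn carriership.
#'
#' @param n_per_period integer, cultivars per period (recycled over periods).
#' @param carrier_fractions named list: for each group, a numeric vector of
#'   per-period carrier fractions (one per period).
#' @param seed RNG seed.
#' @param groups named list mapping group name to its marker columns.
#' @param periods period labels.
#' @param sc_given_ksn optional probability that a ksn-carrier also carries an
#'   S_C marker (overrides the S_C baseline for ksn carriers).
#' @return marker-panel data.frame (`cultivar`, `period`, logical marker
#'   columns).
#' @export
simulate_panel <- function(n_per_period, carrier_fractions, seed,
                           groups = list(ksn = c("ksn_copia", "ksn_null"),
                                         S_C = paste0("S_C", 1:5)),
                           periods = c("I", "II", "III", "IV", "V"),
                           sc_given_ksn = NULL) {
  set.seed(seed)
  stopifnot(all(names(carrier_fractions) %in% names(groups)))
  for (fr in carrier_fractions) {
    stopifnot(all(fr >= 0), all(fr <= 1), length(fr) == length(periods))
  }
  n_per_period <- rep_len(n_per_period, length(periods))
  markers <- unlist(groups, use.names = FALSE)
  rows <- list()
  cultivar <- 0L
  for (pi in seq_along(periods)) {
    for (i in seq_len(n_per_period[pi])) {
      cultivar <- cultivar + 1L
      row <- stats::setNames(as.list(rep(FALSE, length(markers))), markers)
      ksn_carrier <- FALSE
      for (grp in names(carrier_fractions)) {
        p <- carrier_fractions[[grp]][pi]
        if (grp == "S_C" && !is.null(sc_given_ksn) && ksn_carrier) {
          p <- sc_given_ksn
        }
        if (stats::runif(1) < p) {
          pick <- sample(groups[[grp]], 1)
          row[[pick]] <- TRUE
          if (grp == "ksn") ksn_carrier <- TRUE
        }
      }
      rows[[cultivar]] <- c(list(cultivar = sprintf("cv%04d", cultivar),
                                 period = periods[pi]), row)
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Introduce a fixed number of substitutions into a sequence
#'
#' Exactly `n_snps` substitutions at distinct, uniformly chosen positions,
#' never to the original character.
#'
#' @param seq character string.
#' @param n_snps number of substitutions (at most the sequence length).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param alphabet characters to substitute from; defaults to A/C/G/T when the
#'   sequence is DNA-like, else the 20 amino-acid letters.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(seq, n_snps, seed = NULL, alphabet = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq),
            n_snps >= 0)
  chars <- strsplit(seq, "")[[1]]
  if (n_snps > length(chars)) stop("n_snps exceeds the sequence length")
  if (is.null(alphabet)) {
    alphabet <- if (all(chars %in% .DNA4)) .DNA4 else .AA20
  }
  if (n_snps == 0) return(seq)
  pos <- sample(length(chars), n_snps)
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

.random_seq <- function(length, alphabet) {
  paste(sample(alphabet, length, replace = TRUE), collapse = "")
}

#' Simulate an allele set with a target pairwise divergence
#'
#' Alleles are independent mutants of a common ancestral sequence. The
#' per-allele substitution count is chosen so that the expected pairwise
#' difference fraction between two alleles equals `target_divergence`,
#' accounting for back-coincident substitutions at shared sites.
#'
#' @param length sequence length.
#' @param n_alleles number of alleles.
#' @param target_divergence expected pairwise difference fraction in `[0, 1)`.
#' @param seed RNG seed.
#' @param alphabet residue alphabet (default the 20 amino acids).
#' @return character vector of `n_alleles` sequences.
#' @export
simulate_allele_set <- function(length, n_alleles, target_divergence, seed,
                                alphabet = .AA20) {
  set.seed(seed)
  stopifnot(target_divergence >= 0, target_divergence < 1, n_alleles >= 2)
  base <- .random_seq(length, alphabet)
  k <- base::length(alphabet)
  # expected pairwise diff for per-allele rate d': 2d'(1-d') + d'^2 (k-2)/(k-1)
  d <- target_divergence
  dprime <- if (d == 0) 0 else {
    ((k - 1) / k) * (1 - sqrt(max(0, 1 - d * k / (k - 1))))
  }
  n_snps <- round(length * dprime)
  vapply(seq_len(n_alleles), function(i) mutate_sequence(base, n_snps),
         character(1))
}

#' Simulate a genome-screen fixture with known candidate archetypes
#'
#' Emits four candidate genes whose expected screening outcome is fixed by
#' construction: two S-RNase-like archetypes (pistil-specific, highly
#' expressed, highly divergent alleles) that [rank_candidates()] must call
#' PRIMARY, and two relic archetypes (low divergence; one weakly expressed)
#' that must be rejected. References are moderately diverged relatives of the
#' candidates' ancestral sequence.
#'
#' @param seed RNG seed.
#' @param length protein length of the simulated alleles.
#' @return `list(genes = <list of candidate_gene>, references = <character>)`.
#' @export
simulate_screen_fixture <- function(seed, length = 200L) {
  set.seed(seed)
  base <- .random_seq(length, .AA20)
  k <- base::length(.AA20)
  rate_for <- function(d) ((k - 1) / k) * (1 - sqrt(max(0, 1 - d * k / (k - 1))))
  alleles_at <- function(n, d) {
    vapply(seq_len(n), function(i) {
      mutate_sequence(base, round(length * rate_for(d)))
    }, character(1))
  }
  expr <- function(pistil, stamen, sd_frac = 0.03) {
    data.frame(tissue = c("pistil", "stamen"),
               mean_fpkm = pmax(0, stats::rnorm(2, c(pistil, stamen),
                                                sd_frac * c(pistil, stamen) + 0.01)),
               se_fpkm = c(2, 0.2), n_reps = 3L)
  }
  genes <- list(
    candidate_gene("sim3D", alleles = alleles_at(4, 0.35),
                   expression = expr(150, 0)),
    candidate_gene("sim0A", alleles = alleles_at(3, 0.37),
                   expression = expr(120, 0.5)),
    candidate_gene("sim3A", alleles = alleles_at(3, 0.02),
                   expression = expr(30, 0)),
    candidate_gene("sim6C", alleles = alleles_at(3, 0.05),
                   expression = expr(75, 0.5))
  )
  refs <- vapply(1:2, function(i) {
    mutate_sequence(base, round(length * 0.45))
  }, character(1))
  names(refs) <- c("ref_SRNase_1", "ref_SRNase_2")
  list(genes = genes, references = refs)
}
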