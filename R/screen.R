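# Candidate S-RNase / SLF screening: pairwise identity and allelic divergence,
# expression classing and pistil specificity, ORF/pseudogene checks, SLF-vs-FBX
# haplotype-sharing typing, locus span, and allele-origin tracing.

# ---- candidate gene container -----------------------------------------------

#' Candidate gene record for S-RNase screening
#'
#' @param name gene name.
#' @param alleles named or unnamed character vector of allele sequences
#'   (protein or nucleotide).
#' @param expression data.frame with columns `tissue`, `mean_fpkm` and
#'   optionally `se_fpkm`, `n_reps`.
#' @param chromosome,start,end optional 1-based coordinates (strand may be
#'   encoded by `start > end`).
#' @param flags character vector, subset of `c("PSEUDOGENE", "TRUNCATED")`.
#' @return an object of class `"candidate_gene"`.
#' @export
candidate_gene <- function(name, alleles = character(0),
                           expression = data.frame(tissue = character(0),
                                                   mean_fpkm = numeric(0)),
                           chromosome = NA_character_, start = NA_real_,
                           end = NA_real_, flags = character(0)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(alleles),
            is.data.frame(expression),
            all(c("tissue", "mean_fpkm") %in% names(expression)))
  if (any(expression$mean_fpkm < 0, na.rm = TRUE)) {
    stop("mean FPKM must be non-negative")
  }
  structure(list(name = name, alleles = alleles, expression = expression,
                 chromosome = chromosome, start = start, end = end,
                 flags = flags),
            class = "candidate_gene")
}

# ---- pairwise identity ------------------------------------------------------

#' Percent identity of two sequences under global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and a linear
#' gap cost of 1 per residue; identity = matches / alignment columns x 100,
#' reported to one decimal. Alignment columns include internal gaps but
#' exclude terminal overhangs, so for equal-length SNP-only comparisons the
#' value reduces to (L - SNPs) / L.
#'
#' @param seqA,seqB non-empty character strings over a common alphabet.
#' @return percent identity (one decimal).
#' @examples
#' pairwise_identity("ACGTACGT", "ACGAACGT")  # 87.5
#' @export
pairwise_identity <- function(seqA, seqB) {
  stopifnot(is.character(seqA), length(seqA) == 1L,
            is.character(seqB), length(seqB) == 1L)
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be non-empty")
  al <- .align_global(seqA, seqB)
  stats <- .alignment_identity(al$a, al$b)
  round_half_up(100 * stats$matches / stats$columns, 1)
}

# global alignment; returns the two gapped strings
.align_global <- function(seqA, seqB) {
  letters_ab <- sort(unique(c(strsplit(seqA, "")[[1]], strsplit(seqB, "")[[1]])))
  mat <- diag(1, length(letters_ab))
  dimnames(mat) <- list(letters_ab, letters_ab)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(seqA), Biostrings::BString(seqB),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

# matches and columns after trimming terminal overhangs (end runs of gaps)
.alignment_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  both <- ca != "-" & cb != "-"
  first <- which(both)[1]
  last <- utils::tail(which(both), 1)
  idx <- first:last
  list(matches = sum(ca[idx] == cb[idx] & ca[idx] != "-"),
       columns = length(idx))
}

#' Mean pairwise identity over all allele pairs of a gene
#'
#' High allelic divergence (low mean identity) is one of the screening criteria
#' for a true S-RNase, whose alleles are among the most divergent sequences in
#' plant genomes.
#'
#' @param gene a [candidate_gene()] with at least two alleles, or a character
#'   vector of allele sequences.
#' @return unweighted mean of [pairwise_identity()] over unordered pairs,
#'   one decimal.
#' @export
average_divergence <- function(gene) {
  alleles <- if (inherits(gene, "candidate_gene")) gene$alleles else gene
  if (length(alleles) < 2L) stop("need >= 2 alleles to compute divergence")
  pairs <- utils::combn(length(alleles), 2)
  ids <- apply(pairs, 2, function(ij) {
    pairwise_identity(alleles[[ij[1]]], alleles[[ij[2]]])
  })
  round_half_up(mean(ids), 1)
}

# ---- expression -------------------------------------------------------------

#' Expression class of a mean FPKM value
#'
#' Bins: `"***"` above 100, `"**"` in (50, 100], `"*"` in \[10, 50\], `"NONE"`
#' below 10 (and in (50, 50]-gaps none exist). Boundaries are half-open
#' downward so the conventional 50-100 / 10-50 printed bins do not overlap.
#'
#' @param mean_fpkm non-negative mean FPKM.
#' @return one of `"***"`, `"**"`, `"*"`, `"NONE"`.
#' @export
expression_class <- function(mean_fpkm) {
  stopifnot(is.numeric(mean_fpkm), length(mean_fpkm) == 1L, is.finite(mean_fpkm))
  if (mean_fpkm < 0) stop("mean FPKM must be non-negative")
  if (mean_fpkm > 100) "***"
  else if (mean_fpkm > 50) "**"
  else if (mean_fpkm >= 10) "*"
  else "NONE"
}

#' Is a gene's expression pistil-specific?
#'
#' True iff the pistil mean FPKM is at least `pistil_min` and every non-pistil
#' tissue mean is below `other_max`. Thresholds default to values separating
#' the S-RNase pattern (pistil 44-100, stamen 0) from the SLF pattern (stamen
#' 4-22, pistil 0-1).
#'
#' @param gene a [candidate_gene()] whose `expression` table contains a
#'   `"pistil"` row and at least one other tissue.
#' @param pistil_min,other_max FPKM thresholds.
#' @return logical.
#' @export
pistil_specific <- function(gene, pistil_min = 10, other_max = 2) {
  stopifnot(inherits(gene, "candidate_gene"))
  expr <- gene$expression
  pist <- expr$mean_fpkm[expr$tissue == "pistil"]
  if (!length(pist)) stop("missing tissue: no pistil expression record")
  other <- expr$mean_fpkm[expr$tissue != "pistil"]
  if (!length(other)) stop("missing tissue: need >= 1 non-pistil record")
  mean(pist) >= pistil_min && all(other < other_max)
}

# ---- ranking ----------------------------------------------------------------

#' Rank candidate genes for S-RNase status
#'
#' A gene is a PRIMARY candidate iff it is pistil-specific, its pistil
#' expression class is `"***"` or `"**"`, its mean allelic identity is below
#' `divergence_cutoff`, and its best identity to any reference S-RNase is at
#' least `reference_cutoff`. Rejected genes list the criteria they failed.
#'
#' @param genes list of [candidate_gene()] objects.
#' @param references non-empty character vector of reference S-RNase sequences
#'   (e.g. Prunus S-RNase proteins).
#' @param divergence_cutoff maximum mean allelic identity (%) for a candidate.
#' @param reference_cutoff minimum best reference identity (%).
#' @return data.frame, one row per gene: `gene`, `pistil_specific`,
#'   `expr_class`, `avg_identity`, `best_ref_identity`, `status`, `failed`;
#'   PRIMARY rows sort first.
#' @export
rank_candidates <- function(genes, references, divergence_cutoff = 80,
                            reference_cutoff = 30) {
  stopifnot(is.list(genes), length(genes) > 0,
            is.character(references), length(references) > 0)
  rows <- lapply(genes, function(g) {
    stopifnot(inherits(g, "candidate_gene"))
    ps <- tryCatch(pistil_specific(g), error = function(e) NA)
    pist <- g$expression$mean_fpkm[g$expression$tissue == "pistil"]
    cls <- if (length(pist)) expression_class(mean(pist)) else "NONE"
    div <- if (length(g$alleles) >= 2L) average_divergence(g) else NA_real_
    best_ref <- if (length(g$alleles)) {
      max(vapply(references, function(r) {
        max(vapply(g$alleles, pairwise_identity, numeric(1), seqB = r))
      }, numeric(1)))
    } else {
      NA_real_
    }
    failed <- character(0)
    if (!isTRUE(ps)) failed <- c(failed, "pistil_specificity")
    if (!cls %in% c("***", "**")) failed <- c(failed, "expression_level")
    if (!isTRUE(div < divergence_cutoff)) failed <- c(failed, "allelic_divergence")
    if (!isTRUE(best_ref >= reference_cutoff)) failed <- c(failed, "reference_similarity")
    data.frame(gene = g$name, pistil_specific = isTRUE(ps), expr_class = cls,
               avg_identity = div, best_ref_identity = best_ref,
               status = if (length(failed)) "REJECTED" else "PRIMARY",
               failed = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$status != "PRIMARY", out$avg_identity), , drop = FALSE]
}

# ---- ORF / pseudogene -------------------------------------------------------

.STOPS <- c("TAA", "TAG", "TGA")

# ATG..stop ORF lengths (bases, incl. stop) in all 6 frames; open-ended ORFs
# (no stop before the sequence end) are counted to the end
.orf_lengths <- function(dna) {
  lens <- integer(0)
  for (s in c(dna, .revcomp(dna))) {
    chars <- strsplit(s, "")[[1]]
    for (off in 0:2) {
      idx <- seq(off + 1L, length(chars))
      n <- (length(idx) %/% 3L) * 3L
      if (n < 3L) next
      codons <- apply(matrix(chars[idx[1:n]], nrow = 3), 2, paste, collapse = "")
      i <- 1L
      while (i <= length(codons)) {
        if (codons[i] == "ATG") {
          stop_at <- which(codons[i:length(codons)] %in% .STOPS)[1]
          if (is.na(stop_at)) {
            lens <- c(lens, 3L * (length(codons) - i + 1L))
            break
          }
          lens <- c(lens, 3L * stop_at)
          i <- i + stop_at
        } else {
          i <- i + 1L
        }
      }
    }
  }
  lens
}

.revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Flag truncated and pseudogene coding sequences
#'
#' Scans all six frames for ATG-initiated open reading frames. `TRUNCATED` is
#' flagged when no ORF reaches `min_orf` bases; `PSEUDOGENE` when a declared
#' full-length expectation is given and the longest ORF terminates before it —
#' the signature of a frameshift-induced premature stop.
#'
#' @param cds nucleotide sequence (A/C/G/T/N, case-insensitive).
#' @param min_orf minimum ORF length in bases (default 1000).
#' @param expected_length expected full-length ORF in bases, or `NULL`.
#' @return character vector of flags (possibly empty).
#' @export
orf_pseudogene_check <- function(cds, min_orf = 1000L, expected_length = NULL) {
  stopifnot(is.character(cds), length(cds) == 1L, nzchar(cds))
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds)) stop("non-DNA characters in sequence")
  lens <- .orf_lengths(cds)
  longest <- if (length(lens)) max(lens) else 0L
  flags <- character(0)
  if (longest < min_orf) flags <- c(flags, "TRUNCATED")
  if (!is.null(expected_length) && longest < expected_length) {
    flags <- c(flags, "PSEUDOGENE")
  }
  flags
}

# ---- F-box typing and locus span --------------------------------------------

#' Classify an F-box gene group as SLF or FBX by haplotype sharing
#'
#' A pollen-side F-box group shared by at least `min_shared` of the
#' `universe_size` S-haplotypes surveyed is an SLF (S-locus F-box participating
#' in collaborative non-self recognition); sparser groups, including the
#' exactly-three-of-six case, are FBX.
#'
#' @param present_in character vector (or count) of S-haplotypes carrying the
#'   group.
#' @param universe_size number of S-haplotypes surveyed (default 6).
#' @param min_shared sharing threshold (default 4).
#' @return `"SLF"` or `"FBX"`.
#' @export
classify_fbox <- function(present_in, universe_size = 6L, min_shared = 4L) {
  n <- if (is.numeric(present_in)) as.integer(present_in) else length(unique(present_in))
  if (n > universe_size) stop("more haplotypes present than in the universe")
  if (n >= min_shared) "SLF" else "FBX"
}

#' Physical span of the S-locus features of one haplotype
#'
#' Orientation-agnostic: uses both `start` and `end` of every selected row, so
#' strand flips (start/end swaps) never change the result.
#'
#' @param features data.frame with columns `s_genotype`, `start`, `end` (e.g.
#'   as read by [read_features()]).
#' @param haplotype_label S-haplotype label selecting rows.
#' @return span in bp (max coordinate minus min coordinate).
#' @export
locus_span <- function(features, haplotype_label) {
  stopifnot(is.data.frame(features),
            all(c("s_genotype", "start", "end") %in% names(features)))
  rows <- features[features$s_genotype == haplotype_label, , drop = FALSE]
  if (!nrow(rows)) stop("empty selection: no features carry label '",
                        haplotype_label, "'")
  coords <- c(rows$start, rows$end)
  max(coords) - min(coords)
}

# ---- allele-origin tracing --------------------------------------------------

#' Trace a cultivar allele to candidate wild-source sequences
#'
#' Compares the query allele against per-species hit sequences: 100% identity
#' is a full match (the wild individual carries the cultivar allele), lower
#' identity is a near match reported with its SNP count, and an absent species
#' entry means no amplification.
#'
#' @param query non-empty query sequence.
#' @param wild_hits named list/vector of per-species sequences; use `NA` or
#'   `NULL` for species without amplification.
#' @return data.frame with columns `species`, `status` (`MATCH_100`,
#'   `NEAR_MATCH`, `NO_AMPLIFICATION`), `identity`, `snps`.
#' @export
trace_allele_origin <- function(query, wild_hits) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query))
  if (!length(wild_hits)) {
    return(data.frame(species = character(0), status = character(0),
                      identity = numeric(0), snps = integer(0)))
  }
  if (is.null(names(wild_hits))) stop("wild_hits must be named by species")
  rows <- lapply(names(wild_hits), function(sp) {
    hit <- wild_hits[[sp]]
    if (is.null(hit) || length(hit) == 0L || is.na(hit) || !nzchar(hit)) {
      return(data.frame(species = sp, status = "NO_AMPLIFICATION",
                        identity = NA_real_, snps = NA_integer_))
    }
    al <- .align_global(query, hit)
    st <- .alignment_identity(al$a, al$b)
    identity <- round_half_up(100 * st$matches / st$columns, 1)
    mism <- st$columns - st$matches
    data.frame(species = sp,
               status = if (mism == 0L) "MATCH_100" else "NEAR_MATCH",
               identity = identity, snps = as.integer(mism))
  })
  do.call(rbind, rows)
}
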