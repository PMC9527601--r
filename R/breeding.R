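# Marker-based genotype calling (S-alleles, KSN types, ap2) and historical
# introgression analysis over breeding periods.

.S_MARKERS <- paste0("S_C", 1:5)

#' Call the S-genotype of a cultivar from allele-specific markers
#'
#' Presence/absence PCR markers reveal which identified S-alleles a cultivar
#' carries; alleles beyond those are padded with anonymous placeholders up to
#' the ploidy. More present markers than the declared ploidy raises a
#' ploidy-conflict warning (suggesting a triploid) and returns all present
#' alleles.
#'
#' @param presence named logical vector of S-allele markers (e.g.
#'   `c(S_C1 = TRUE, S_C2 = FALSE, ...)`), or a one-row data.frame slice.
#' @param ploidy declared ploidy (default 2).
#' @param anonymous_label placeholder label for unidentified alleles.
#' @return character vector of length `max(ploidy, n_present)`.
#' @examples
#' call_s_genotype(c(S_C1 = TRUE, S_C2 = TRUE, S_C3 = FALSE))
#' @export
call_s_genotype <- function(presence, ploidy = 2L, anonymous_label = "S?") {
  if (is.data.frame(presence)) {
    stopifnot(nrow(presence) == 1L)
    keep <- intersect(names(presence), .S_MARKERS)
    presence <- vapply(presence[keep], isTRUE, logical(1))
  }
  stopifnot(is.logical(presence), !is.null(names(presence)))
  present <- names(presence)[presence %in% TRUE]
  if (length(present) > ploidy) {
    warning("ploidy conflict: ", length(present),
            " S-markers present for declared ploidy ", ploidy,
            " (triploid cultivar?)")
    return(present)
  }
  c(present, rep(anonymous_label, ploidy - length(present)))
}

#' Classify the KSN genotype from allele-specific markers
#'
#' Maps the presence pattern of the three KSN markers (`ksn_copia`, `ksn_null`,
#' `KSN_W`) onto the five diploid KSN types under the dosage assumption that a
#' single present non-functional marker without the wild allele is homozygous:
#' Type 1 = copia/null, 2 = copia/copia, 3 = null/null, 4 = copia/W,
#' 5 = W/W. Types 1-3 are continuous-flowering (CF), 4-5 once-flowering (OF).
#' The null+W pattern is unclassifiable (`"unknown"`), all three present flags
#' a triploid, and all absent is missing data.
#'
#' @param copia,null,W logical marker presences, or `copia` may be a named
#'   logical vector / one-row data.frame with entries `ksn_copia`, `ksn_null`,
#'   `KSN_W`.
#' @return `list(type = 1..5 or NA, phenotype = "CF"/"OF"/NA, status)` where
#'   `status` is `"ok"`, `"unknown"`, `"missing"` or `"triploid"`.
#' @export
classify_ksn <- function(copia, null = NULL, W = NULL) {
  if (is.data.frame(copia)) {
    stopifnot(nrow(copia) == 1L)
    copia <- vapply(copia[c("ksn_copia", "ksn_null", "KSN_W")], isTRUE, logical(1))
  }
  if (is.logical(copia) && length(copia) == 3L && !is.null(names(copia))) {
    null <- copia[["ksn_null"]]
    W <- copia[["KSN_W"]]
    copia <- copia[["ksn_copia"]]
  }
  stopifnot(is.logical(copia), is.logical(null), is.logical(W))
  key <- paste0(as.integer(copia), as.integer(null), as.integer(W))
  switch(key,
    "110" = list(type = 1L, phenotype = "CF", status = "ok"),
    "100" = list(type = 2L, phenotype = "CF", status = "ok"),
    "010" = list(type = 3L, phenotype = "CF", status = "ok"),
    "101" = list(type = 4L, phenotype = "OF", status = "ok"),
    "001" = list(type = 5L, phenotype = "OF", status = "ok"),
    "011" = list(type = NA_integer_, phenotype = NA_character_, status = "unknown"),
    "000" = list(type = NA_integer_, phenotype = NA_character_, status = "missing"),
    "111" = list(type = NA_integer_, phenotype = NA_character_, status = "triploid"))
}

#' Map breeding years to the five historical periods
#'
#' Periods: I before 1850, II 1850-1900, III 1900-1940, IV 1940-1980,
#' V 1980 onward (closed lower bounds: 1850 is period II; the modern period is
#' open-ended).
#'
#' @param year integer vector of breeding years.
#' @return factor with levels `I..V`.
#' @export
year_to_period <- function(year) {
  cut(as.numeric(year), breaks = c(-Inf, 1850, 1900, 1940, 1980, Inf),
      labels = c("I", "II", "III", "IV", "V"), right = FALSE)
}

.panel_period <- function(panel) {
  if ("period" %in% names(panel)) {
    factor(as.character(panel$period), levels = c("I", "II", "III", "IV", "V"))
  } else if ("year" %in% names(panel)) {
    year_to_period(panel$year)
  } else {
    stop("panel needs a 'period' or 'year' column")
  }
}

#' Per-period carrier frequencies of a marker group
#'
#' A cultivar is a carrier when at least one marker of the group is present.
#' Periods with no cultivars are excluded (with a notice attribute).
#'
#' @param panel marker-panel data.frame: a `period` (I-V) or `year` column plus
#'   logical marker columns (see [read_marker_panel()]).
#' @param marker_group character vector of marker column names (e.g.
#'   `c("ksn_copia", "ksn_null")`).
#' @return data.frame of class `"period_freq"` with columns `period`, `n`,
#'   `carriers`, `fraction`.
#' @export
period_frequencies <- function(panel, marker_group) {
  stopifnot(is.data.frame(panel), is.character(marker_group),
            all(marker_group %in% names(panel)))
  period <- .panel_period(panel)
  if (anyNA(period)) stop("some rows have no resolvable breeding period")
  carrier <- Reduce(`|`, lapply(marker_group, function(m) panel[[m]] %in% TRUE))
  out <- data.frame(period = levels(period),
                    n = as.integer(table(period)),
                    carriers = as.integer(tapply(carrier, period, sum, default = 0)))
  empty <- out$n == 0L
  if (any(empty)) {
    attr(out, "notice") <- paste("excluded empty period(s):",
                                 paste(out$period[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  out$fraction <- out$carriers / out$n
  class(out) <- c("period_freq", "data.frame")
  attr(out, "marker_group") <- marker_group
  out
}

#' @export
print.period_freq <- function(x, ...) {
  cat("Carrier frequency by breeding period (markers: ",
      paste(attr(x, "marker_group"), collapse = ", "), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  if (!is.null(attr(x, "notice"))) cat(attr(x, "notice"), "\n")
  invisible(x)
}

#' Plot per-period carrier frequencies
#' @param x a `"period_freq"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.period_freq <- function(x, ...) {
  graphics::plot(seq_len(nrow(x)), x$fraction, type = "b", pch = 19,
                 xaxt = "n", ylim = c(0, 1), xlab = "Breeding period",
                 ylab = "Fraction of carrier cultivars", ...)
  graphics::axis(1, at = seq_len(nrow(x)),
                 labels = paste0(x$period, "\n(n=", x$n, ")"), padj = 0.5)
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computed directly from the hypergeometric distribution: the p-value sums
#' the probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (standard two-sided convention).
#' A table with a zero margin is degenerate and returns p = 1.
#'
#' @param a,b,c,d cell counts of the table `[[a, b], [c, d]]`.
#' @return `list(p_value, degenerate)`.
#' @examples
#' fisher_exact_2x2(3, 0, 0, 3)  # p = 0.1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(p_value = 1, degenerate = TRUE))
  }
  lo <- max(0, c1 - r2)
  hi <- min(c1, r1)
  x <- lo:hi
  probs <- stats::dhyper(x, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  list(p_value = min(1, sum(probs[probs <= obs * (1 + 1e-7)])),
       degenerate = FALSE)
}
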