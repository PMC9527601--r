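# Haplotype and plant-genotype containers used by the GSI transmission model.
#
# An S-allele is a plain character label; anonymity (wildcard alleles that never
# match any concrete allele nor each other in SI recognition) is carried as an
# attribute on each haplotype. Trait alleles at linked loci (KSN, AP2, ...) are
# labels whose functionality is looked up in a small package-level registry.

.trait_registry <- new.env(parent = emptyenv())

.default_trait_alleles <- function() {
  list(
    KSN = c(KSN_W = TRUE, ksn_copia = FALSE, ksn_null = FALSE, ksn = FALSE),
    AP2 = c(AP2_W = TRUE, ap2 = FALSE)
  )
}

.reset_trait_registry <- function() {
  rm(list = ls(.trait_registry), envir = .trait_registry)
  defaults <- .default_trait_alleles()
  for (locus in names(defaults)) {
    assign(locus, defaults[[locus]], envir = .trait_registry)
  }
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  .reset_trait_registry()
}

#' Register a trait allele and its functionality
#'
#' The registry maps each allele label at a linked locus to a logical
#' `functional` flag. Alleles for `KSN` (`KSN_W` functional; `ksn_copia`,
#' `ksn_null`, `ksn` non-functional) and `AP2` (`AP2_W` functional, `ap2`
#' non-functional) are pre-registered.
#'
#' @param locus locus name, e.g. `"KSN"`.
#' @param allele allele label.
#' @param functional logical flag.
#' @return invisibly, the updated allele table for the locus.
#' @export
register_trait_allele <- function(locus, allele, functional) {
  stopifnot(is.character(locus), length(locus) == 1L, nzchar(locus),
            is.character(allele), length(allele) == 1L, nzchar(allele),
            is.logical(functional), length(functional) == 1L, !is.na(functional))
  tab <- if (exists(locus, envir = .trait_registry)) {
    get(locus, envir = .trait_registry)
  } else {
    logical(0)
  }
  tab[allele] <- functional
  assign(locus, tab, envir = .trait_registry)
  invisible(tab)
}

#' Look up whether a trait allele is functional
#'
#' @param locus locus name.
#' @param allele allele label.
#' @return `TRUE`/`FALSE`, or `NA` for an unregistered allele.
#' @export
trait_functional <- function(locus, allele) {
  if (!exists(locus, envir = .trait_registry)) return(NA)
  tab <- get(locus, envir = .trait_registry)
  if (!allele %in% names(tab)) return(NA)
  unname(tab[[allele]])
}

#' Is an S-allele label anonymous by default?
#'
#' Labels `S_x`, `S_y`, `Sx`, `Sy` and labels beginning with `"S?"` denote
#' anonymous (unidentified) S-alleles: they are wildcards that never match a
#' concrete allele, nor another anonymous label, in SI pollen recognition.
#'
#' @param label character vector of S-allele labels.
#' @return logical vector.
#' @export
is_anonymous_s <- function(label) {
  label %in% c("S_x", "S_y", "Sx", "Sy") | startsWith(label, "S?")
}

#' Construct a phased haplotype
#'
#' A haplotype couples one S-allele with the alleles it carries at linked trait
#' loci (passed as named arguments, e.g. `KSN = "ksn_copia"`).
#'
#' @param s S-allele label (non-empty string).
#' @param ... named trait-locus alleles, one per locus.
#' @param anonymous logical; whether `s` is an anonymous allele. Defaults to
#'   [is_anonymous_s()] on the label.
#' @return an object of class `"haplotype"`.
#' @examples
#' haplotype("S_C1", KSN = "ksn_copia")
#' @export
haplotype <- function(s, ..., anonymous = is_anonymous_s(s)) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  traits <- c(...)
  if (length(traits)) {
    if (is.null(names(traits)) || any(!nzchar(names(traits)))) {
      stop("trait alleles must be passed as named arguments (locus = allele)")
    }
    if (anyDuplicated(names(traits))) {
      stop("at most one allele per locus in a haplotype")
    }
    traits <- vapply(traits, as.character, character(1))
  } else {
    traits <- character(0)
  }
  structure(list(s = s, anonymous = isTRUE(anonymous), traits = traits),
            class = "haplotype")
}

#' @export
format.haplotype <- function(x, ...) {
  tr <- if (length(x$traits)) {
    paste0(" [", paste(names(x$traits), x$traits, sep = "=", collapse = ", "), "]")
  } else ""
  paste0(x$s, if (x$anonymous) "?" else "", tr)
}

#' @export
print.haplotype <- function(x, ...) {
  cat("<haplotype>", format(x), "\n")
  invisible(x)
}

# canonical key used to merge identical gametes / offspring genotypes
.hap_key <- function(h) {
  if (!length(h$traits)) return(h$s)
  tr <- h$traits[order(names(h$traits))]
  paste0(h$s, "|", paste(names(tr), tr, sep = "=", collapse = ";"))
}

.allele_at <- function(h, locus) {
  if (identical(locus, "S")) return(h$s)
  if (!locus %in% names(h$traits)) {
    stop("locus '", locus, "' absent from haplotype", call. = FALSE)
  }
  unname(h$traits[[locus]])
}

#' Construct a ploidy-aware plant genotype
#'
#' @param id plant identifier.
#' @param ... haplotypes built with [haplotype()] (or a single list of them).
#' @param ploidy integer in `{2, 3, 4}`; defaults to the number of haplotypes.
#' @return an object of class `"plant_genotype"`.
#' @examples
#' plant_genotype("OB", haplotype("S_C1", KSN = "ksn_copia"),
#'                      haplotype("S_C2", KSN = "ksn_null"))
#' @export
plant_genotype <- function(id, ..., ploidy = NULL) {
  haps <- list(...)
  if (length(haps) == 1L && is.list(haps[[1]]) && !inherits(haps[[1]], "haplotype")) {
    haps <- haps[[1]]
  }
  if (!length(haps) || !all(vapply(haps, inherits, logical(1), "haplotype"))) {
    stop("haplotypes must be built with haplotype()")
  }
  if (is.null(ploidy)) ploidy <- length(haps)
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(2L, 3L, 4L)) stop("ploidy must be 2, 3 or 4")
  if (length(haps) != ploidy) {
    stop("number of haplotypes (", length(haps), ") must equal ploidy (", ploidy, ")")
  }
  loci <- lapply(haps, function(h) sort(names(h$traits)))
  if (length(unique(loci)) != 1L) {
    stop("all haplotypes of one plant must carry the same trait loci")
  }
  structure(list(id = as.character(id), ploidy = ploidy, haplotypes = haps),
            class = "plant_genotype")
}

#' @export
print.plant_genotype <- function(x, ...) {
  cat("<plant_genotype> ", x$id, " (", c("haploid", "diploid", "triploid",
      "tetraploid")[x$ploidy], ")\n", sep = "")
  for (h in x$haplotypes) cat("  ", format(h), "\n", sep = "")
  invisible(x)
}

#' S-allele labels of a plant
#' @param plant a [plant_genotype()].
#' @return character vector of length `ploidy`.
#' @export
s_alleles <- function(plant) {
  stopifnot(inherits(plant, "plant_genotype"))
  vapply(plant$haplotypes, function(h) h$s, character(1))
}

#' Construct a recombination map
#'
#' Maps each linked trait locus to its recombination fraction with the S-locus.
#' Loci without an entry default to `r = 0.5` (unlinked) wherever the map is
#' consumed.
#'
#' @param ... named recombination fractions in `[0, 0.5]`, e.g. `KSN = 0.2`.
#' @return a named numeric vector of class `"recomb_map"`.
#' @examples
#' recomb_map(KSN = 0.2, AP2 = 0.13)
#' @export
recomb_map <- function(...) {
  r <- c(...)
  if (length(r)) {
    if (is.null(names(r)) || any(!nzchar(names(r)))) {
      stop("recombination fractions must be named by locus")
    }
    .check_r(r)
  } else {
    r <- numeric(0)
  }
  structure(r, class = "recomb_map")
}

.check_r <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0) || any(r > 0.5)) {
    stop("recombination fractions must lie in [0, 0.5]", call. = FALSE)
  }
  invisible(r)
}

# fraction for one locus, defaulting to 0.5 (unlinked)
.r_for <- function(rmap, locus) {
  if (is.null(rmap) || !locus %in% names(rmap)) return(0.5)
  r <- unname(rmap[[locus]])
  .check_r(r)
  r
}

# round half away from zero (Table-style integer percent presentation)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
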