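# Readers and writers for the table and sequence formats the analyses consume:
# FASTA, plant genotype tables, seed-count tables, F1 tables, genetic-map
# marker tables, feature tables (S-locus coordinates), expression tables,
# marker panels (with unicode presence glyphs) and recombination maps.
#
# All tables are TSV or CSV, auto-detected by extension; coordinates are
# 1-based inclusive with strand encoded by start > end.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_delim <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = .delim_for(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8", comment.char = "", quote = "\"", ...)
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

# ---- FASTA ------------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Wrapping is normalized away; record order is preserved. Duplicate ids and
#' empty records are rejected.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  starts <- grep("^>", lines)
  if (!length(starts) || starts[1] != 1L) {
    stop("malformed FASTA (line ", if (length(starts)) 1 else NA,
         "): expected a '>' header first")
  }
  ids <- sub("^>\\s*", "", lines[starts])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(i) {
    if (ends[i] < starts[i] + 1L) return("")
    paste(lines[(starts[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  seqs <- gsub("\\s", "", seqs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty FASTA record(s): ", paste(ids[empty], collapse = ", "))
  }
  bad <- grepl("[^A-Za-z*.-]", seqs)
  if (any(bad)) {
    stop("illegal characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    idx <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, idx, pmin(idx + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- presence glyphs --------------------------------------------------------

#' Parse presence/absence tokens to logical
#'
#' Accepts the filled-circle/cross glyphs used in printed marker panels as well
#' as 1/0 and true/false.
#'
#' @param x character (or logical) vector.
#' @return logical vector; unrecognized tokens become `NA`.
#' @export
parse_presence <- function(x) {
  if (is.logical(x)) return(x)
  tok <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(tok))
  out[tok %in% c("●", "1", "true", "t", "yes", "+")] <- TRUE
  out[tok %in% c("×", "x", "0", "false", "f", "no", "-")] <- FALSE
  out
}

# ---- plants -----------------------------------------------------------------

#' Read a plant genotype table
#'
#' Long format: columns `plant_id`, `ploidy`, `hap_index`, `s_allele`, then one
#' column per trait locus. Each plant must have `ploidy` rows (one per
#' haplotype).
#'
#' @param path TSV/CSV file.
#' @return named list of [plant_genotype()] objects.
#' @export
read_plants <- function(path) {
  df <- .read_delim(path)
  .require_cols(df, c("plant_id", "ploidy", "hap_index", "s_allele"),
                "plant table")
  trait_cols <- setdiff(names(df), c("plant_id", "ploidy", "hap_index", "s_allele"))
  plants <- list()
  for (id in unique(df$plant_id)) {
    rows <- df[df$plant_id == id, , drop = FALSE]
    rows <- rows[order(rows$hap_index), , drop = FALSE]
    ploidy <- unique(rows$ploidy)
    if (length(ploidy) != 1L || nrow(rows) != ploidy) {
      stop("plant '", id, "': haplotype rows (", nrow(rows),
           ") must match a single declared ploidy")
    }
    haps <- lapply(seq_len(nrow(rows)), function(i) {
      traits <- stats::setNames(as.character(unlist(rows[i, trait_cols])),
                                trait_cols)
      traits <- traits[!is.na(traits) & nzchar(traits)]
      do.call(haplotype, c(list(s = rows$s_allele[i]), as.list(traits)))
    })
    plants[[id]] <- plant_genotype(id, haps, ploidy = as.integer(ploidy))
  }
  plants
}

#' Write plant genotypes in the long table format read by [read_plants()]
#' @param plants named list of [plant_genotype()] objects.
#' @param path output TSV/CSV path.
#' @return invisibly, `path`.
#' @export
write_plants <- function(plants, path) {
  loci <- sort(unique(unlist(lapply(plants, function(p) {
    names(p$haplotypes[[1]]$traits)
  }))))
  rows <- list()
  for (p in plants) {
    for (i in seq_along(p$haplotypes)) {
      h <- p$haplotypes[[i]]
      row <- list(plant_id = p$id, ploidy = p$ploidy, hap_index = i,
                  s_allele = h$s)
      for (loc in loci) {
        row[[loc]] <- if (loc %in% names(h$traits)) h$traits[[loc]] else NA
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- seed counts ------------------------------------------------------------

#' Read a seed genotype count table
#'
#' Columns: `cross_id`, `seed_genotype` (strings like `"S_x/S_y"`), `count`.
#'
#' @param path TSV/CSV file.
#' @return data.frame.
#' @export
read_seed_counts <- function(path) {
  df <- .read_delim(path)
  .require_cols(df, c("cross_id", "seed_genotype", "count"), "seed count table")
  if (!is.numeric(df$count) || any(df$count < 0) ||
      any(df$count != round(df$count))) {
    bad <- which(!is.finite(df$count) | df$count < 0 | df$count != round(df$count))
    stop("seed count table: non-integer or negative count at row(s) ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Read a cross description table
#'
#' Columns: `cross_id`, `mother_id`, `mother_genotype`, `father_id`,
#' `father_genotype` (genotypes as `"A/B"` strings), `shared_allele`.
#'
#' @param path TSV/CSV file.
#' @return data.frame.
#' @export
read_crosses <- function(path) {
  df <- .read_delim(path)
  .require_cols(df, c("cross_id", "mother_id", "mother_genotype",
                      "father_id", "father_genotype", "shared_allele"),
                "cross table")
  df
}

#' Assemble seed_genotype_counts objects from cross + count tables
#'
#' @param crosses data.frame from [read_crosses()].
#' @param counts data.frame from [read_seed_counts()].
#' @return named list of [seed_genotype_counts()] objects, each carrying a
#'   `shared_allele` attribute.
#' @export
build_seed_counts <- function(crosses, counts) {
  out <- list()
  for (i in seq_len(nrow(crosses))) {
    cid <- crosses$cross_id[i]
    al <- parse_genotype(crosses$mother_genotype[i])[[1]]
    mother <- plant_genotype(crosses$mother_id[i],
                             haplotype(al[1]), haplotype(al[2]))
    sub <- counts[counts$cross_id == cid, , drop = FALSE]
    obj <- seed_genotype_counts(cid, mother, sub)
    attr(obj, "shared_allele") <- crosses$shared_allele[i]
    out[[cid]] <- obj
  }
  out
}

# ---- F1, markers, features, expression --------------------------------------

#' Read a phased F1 gamete table
#'
#' Columns: `individual`, `parent`, then one column per locus (allele labels;
#' empty/NA = missing call).
#'
#' @param path TSV/CSV file.
#' @param parents named list of [plant_genotype()] objects.
#' @return an [f1_genotype_table()].
#' @export
read_f1 <- function(path, parents) {
  df <- .read_delim(path, na.strings = c("NA", ""))
  .require_cols(df, c("individual", "parent"), "F1 table")
  f1_genotype_table(df, parents)
}

#' Write the gamete table of an [f1_genotype_table()]
#' @param table an [f1_genotype_table()].
#' @param path output TSV/CSV path.
#' @return invisibly, `path`.
#' @export
write_f1 <- function(table, path) {
  utils::write.table(table$gametes, path, sep = .delim_for(path),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a genetic-map marker table (`name`, `cm`, `bp`)
#' @param path TSV/CSV file.
#' @return data.frame.
#' @export
read_markers <- function(path) {
  df <- .read_delim(path)
  .require_cols(df, c("name", "cm", "bp"), "marker table")
  if (any(df$cm < 0, na.rm = TRUE)) stop("marker table: cm must be >= 0")
  if (any(df$bp < 1, na.rm = TRUE)) stop("marker table: bp must be >= 1")
  df
}

#' Read an S-locus feature table
#'
#' Columns: `type`, `gene`, `s_genotype`, `chromosome`, `start`, `end`, and
#' optionally `length`, `annotation`, `stamen_fpkm`, `pistil_fpkm` (plus SE
#' columns). Coordinates are 1-based inclusive; `start > end` encodes the
#' minus strand.
#'
#' @param path TSV/CSV file.
#' @return data.frame.
#' @export
read_features <- function(path) {
  df <- .read_delim(path, na.strings = c("NA", ""))
  .require_cols(df, c("type", "gene", "s_genotype", "chromosome", "start", "end"),
                "feature table")
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 1 | df$end < 1)
  if (length(bad)) {
    stop("feature table: invalid coordinates at row(s) ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Read a tissue expression table (`gene`, `tissue`, `mean_fpkm`, ...)
#' @param path TSV/CSV file.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  df <- .read_delim(path)
  .require_cols(df, c("gene", "tissue", "mean_fpkm"), "expression table")
  if (any(df$mean_fpkm < 0, na.rm = TRUE)) {
    stop("expression table: negative FPKM")
  }
  df
}

# ---- marker panel -----------------------------------------------------------

.PANEL_META <- c("cultivar", "name", "type", "period", "year", "ploidy",
                 "bloom", "flower")

#' Read a cultivar marker panel
#'
#' Metadata columns (`cultivar`/`name`, `period` or `year`, optionally
#' `ploidy`, `type`, `bloom`, `flower`) are kept as-is; every other column is
#' parsed as presence/absence (filled-circle/cross glyphs, 1/0, true/false).
#'
#' @param path TSV/CSV file.
#' @return data.frame with logical marker columns.
#' @export
read_marker_panel <- function(path) {
  df <- .read_delim(path)
  marker_cols <- setdiff(names(df), .PANEL_META)
  for (m in marker_cols) {
    parsed <- parse_presence(df[[m]])
    if (anyNA(parsed) && !anyNA(df[[m]])) {
      bad <- which(is.na(parsed))
      stop("marker panel: unrecognized presence token in column '", m,
           "', row(s) ", paste(bad, collapse = ", "))
    }
    df[[m]] <- parsed
  }
  df
}

#' Write a marker panel with ASCII 1/0 presence encoding
#' @param panel marker-panel data.frame.
#' @param path output TSV/CSV path.
#' @return invisibly, `path`.
#' @export
write_marker_panel <- function(panel, path) {
  out <- panel
  for (m in setdiff(names(out), .PANEL_META)) {
    if (is.logical(out[[m]])) out[[m]] <- as.integer(out[[m]])
  }
  utils::write.table(out, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- recombination map ------------------------------------------------------

#' Read a recombination map (TSV/CSV with columns `locus`, `r`, or YAML)
#' @param path file path; `.yaml`/`.yml` is parsed as a mapping locus -> r.
#' @return a [recomb_map()].
#' @export
read_rmap <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    vals <- yaml::read_yaml(path)
    return(do.call(recomb_map, as.list(vals)))
  }
  df <- .read_delim(path)
  .require_cols(df, c("locus", "r"), "recombination map")
  do.call(recomb_map, as.list(stats::setNames(as.numeric(df$r), df$locus)))
}
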