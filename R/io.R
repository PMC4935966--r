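# Readers and writers for the plain-text formats the pipeline touches:
# GMT gene sets, TSV variant tables, SEG-like segment tables, BED gene
# models and TSV expression matrices. All tables round-trip exactly.

#' Read gene sets from a GMT file
#'
#' MSigDB dialect: one set per line, tab-separated `name`, `description`,
#' then member gene symbols. Duplicate members within a set are dropped.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (one per set).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- list()
    return(structure(out, class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    stop("malformed GMT line (fewer than 3 tab-separated fields) at line(s): ",
         paste(which(n_fields < 3), collapse = ", "))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(sets) == 0)) stop("gene sets must have at least one member")
  names(sets) <- nm
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a variant table from TSV
#'
#' The header must contain the required variant columns (see
#' [variant_table()]); predictor and MAF columns are optional and missing
#' cells become `NA`.
#'
#' @param path Path to a tab-separated table with header.
#' @return A validated [variant_table()].
#' @export
read_variant_table <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  char_cols <- c("chrom", "ref", "alt", "kind", "effect", "gene",
                 .predictor_cols)
  classes <- ifelse(header %in% char_cols, "character", NA)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = classes,
                          na.strings = c("NA", "", "."))
  variant_table(df)
}

#' Write a variant table to TSV
#'
#' @param variants A [variant_table()].
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  df <- as.data.frame(variants)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read CNV segments from a SEG-like TSV
#'
#' Expected columns: `chrom`, `start`, `end`, `copy_number`,
#' `reliability`, and optionally `het_snp_afs` as a semicolon-separated
#' list of allele frequencies. Coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path Path to the table.
#' @param coords Coordinate dialect of the file: `"bed"` (0-based
#'   half-open, default) or `"one_based_closed"`.
#' @return A validated [cnv_segments()] table.
#' @export
read_segments <- function(path, coords = c("bed", "one_based_closed")) {
  coords <- match.arg(coords)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if ("het_snp_afs" %in% names(df)) {
    raw <- as.character(df$het_snp_afs)
    df$het_snp_afs <- lapply(raw, function(s) {
      if (is.na(s) || !nzchar(s)) numeric(0)
      else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  if (coords == "one_based_closed") {
    df$start <- df$start - 1L
  }
  cnv_segments(df)
}

#' Write CNV segments to a SEG-like TSV
#'
#' @param segments A [cnv_segments()] table.
#' @param path Output path.
#' @param coords Coordinate dialect to emit (see [read_segments()]).
#' @export
write_segments <- function(segments, path,
                           coords = c("bed", "one_based_closed")) {
  coords <- match.arg(coords)
  df <- as.data.frame(segments)
  df$het_snp_afs <- vapply(df$het_snp_afs, function(a) {
    paste(format(a, trim = TRUE, digits = 15), collapse = ";")
  }, character(1))
  if (coords == "one_based_closed") df$start <- df$start + 1L
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene models from a BED-like file
#'
#' Columns: `chrom`, `start`, `end`, `symbol`, optional `role`. BED input
#' is 0-based half-open, matching the internal convention. A header line
#' is auto-detected (non-numeric second field).
#'
#' @param path Path to the file.
#' @return A validated [gene_models()] table.
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][2])))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1:4] <- c("chrom", "start", "end", "symbol")
    if (ncol(df) >= 5) names(df)[5] <- "role"
  }
  gene_models(df)
}

#' Read an expression matrix from TSV
#'
#' Genes in rows (first column = symbols), samples in columns.
#'
#' @param path Path to the table.
#' @param unit Unit of the stored values (see [expression_matrix()]).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit = c("TPM", "scaled_estimate")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  expression_matrix(as.matrix(df), unit = unit)
}

#' Write an expression matrix to TSV
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE],
                                                     check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
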