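#' @keywords internal
"_PACKAGE"

# Controlled vocabularies used by validators across the package.
.variant_kinds <- c("SNV", "insertion", "deletion")
.variant_effects <- c("nonsynonymous", "stopgain", "stoploss", "frameshift",
                      "nonframeshift", "splicing", "synonymous", "other")
.nonsilent_effects <- c("nonsynonymous", "stopgain", "stoploss", "frameshift",
                        "nonframeshift", "splicing")
.predictor_cols <- c("sift", "polyphen2", "mutation_taster",
                     "mutation_assessor", "lrt")
.maf_cols <- c("maf_1000g", "maf_esp")
.gene_roles <- c("oncogene", "tumour_suppressor", "other", "unknown")

.required_variant_cols <- c("chrom", "pos", "ref", "alt", "kind", "effect",
                            "gene", "alt_reads", "total_reads",
                            "frac_plus", "frac_minus")

#' Construct and validate a variant table
#'
#' A variant table is a plain `data.frame` with one row per SNV/InDel and a
#' documented set of columns: genomic identity (`chrom`, 1-based `pos`,
#' `ref`, `alt`), `kind` (SNV/insertion/deletion), functional `effect`,
#' `gene` symbol, read support (`alt_reads`, `total_reads`), strand
#' fractions of the supporting reads (`frac_plus`, `frac_minus`), optional
#' tri-state damaging-predictor calls (`sift`, `polyphen2`,
#' `mutation_taster`, `mutation_assessor`, `lrt`; values `"damaging"`,
#' `"benign"` or `NA` for missing) and optional population minor allele
#' frequencies (`maf_1000g`, `maf_esp`; `NA` = not observed in the panel).
#'
#' @param df data.frame holding the required columns (extra columns are
#'   preserved).
#' @return The validated data.frame with class `"variant_table"`.
#' @export
variant_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.required_variant_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c(.predictor_cols, .maf_cols)) {
    if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))
  }
  df$pos <- as.integer(df$pos)
  df$alt_reads <- as.integer(df$alt_reads)
  df$total_reads <- as.integer(df$total_reads)
  for (col in .maf_cols) df[[col]] <- as.numeric(df[[col]])
  for (col in .predictor_cols) df[[col]] <- as.character(df[[col]])

  bad <- which(df$alt_reads > df$total_reads | df$alt_reads < 0)
  if (length(bad) > 0) {
    stop("alt_reads must lie in [0, total_reads]; violated at row(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(!df$kind %in% .variant_kinds)) {
    stop("kind must be one of: ", paste(.variant_kinds, collapse = ", "))
  }
  if (any(!df$effect %in% .variant_effects)) {
    stop("effect must be one of: ", paste(.variant_effects, collapse = ", "))
  }
  frac_ok <- is.na(df$frac_plus) | is.na(df$frac_minus) |
    abs(df$frac_plus + df$frac_minus - 1) < 1e-6
  if (any(!frac_ok)) {
    stop("frac_plus + frac_minus must equal 1 at row(s): ",
         paste(which(!frac_ok), collapse = ", "))
  }
  for (col in .maf_cols) {
    x <- df[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      stop(col, " must lie in [0,1]")
    }
  }
  bad_pred <- vapply(.predictor_cols, function(col) {
    any(!is.na(df[[col]]) & !df[[col]] %in% c("damaging", "benign"))
  }, logical(1))
  if (any(bad_pred)) {
    stop("predictor calls must be 'damaging', 'benign' or NA: ",
         paste(.predictor_cols[bad_pred], collapse = ", "))
  }
  class(df) <- unique(c("variant_table", class(df)))
  df
}

#' Allele frequency of each variant
#'
#' @param variants A [variant_table()].
#' @return Numeric vector `alt_reads / total_reads`.
#' @export
allele_frequency <- function(variants) {
  if (any(variants$total_reads == 0)) {
    stop("allele frequency undefined when total_reads is 0")
  }
  variants$alt_reads / variants$total_reads
}

#' Variant identity keys
#'
#' Variants are identified by `(chrom, pos, ref, alt)` after a
#' reference-free normalisation of InDels: shared trailing bases of
#' ref/alt are trimmed first, then shared leading bases (advancing the
#' position), so equivalent right-padded representations collapse to one
#' key. Full left-alignment against the reference genome is out of scope.
#'
#' @param variants A [variant_table()] (or data.frame with the identity
#'   columns).
#' @return Character vector of keys, `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(variants) {
  n <- nrow(variants)
  ref <- variants$ref
  alt <- variants$alt
  pos <- variants$pos
  out <- character(n)
  for (i in seq_len(n)) {
    norm <- .normalize_allele(pos[i], ref[i], alt[i])
    out[i] <- paste(variants$chrom[i], norm$pos, norm$ref, norm$alt, sep = ":")
  }
  out
}

.normalize_allele <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # trim common suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim common prefix, advancing pos
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Construct and validate a CNV segment table
#'
#' Segments use 0-based half-open intervals internally (BED convention).
#' `het_snp_afs` is a list-column of heterozygous-SNP allele frequencies
#' observed in the tumour within each segment.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`,
#'   `copy_number`, `reliability` and a `het_snp_afs` list-column (may be
#'   empty vectors).
#' @return Validated data.frame with class `"cnv_segments"`.
#' @export
cnv_segments <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("chrom", "start", "end", "copy_number", "reliability")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("segment table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"het_snp_afs" %in% names(df)) {
    df$het_snp_afs <- replicate(nrow(df), numeric(0), simplify = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$copy_number <- as.integer(df$copy_number)
  if (any(df$start >= df$end)) {
    stop("segment intervals must satisfy start < end (0-based half-open); ",
         "row(s): ", paste(which(df$start >= df$end), collapse = ", "))
  }
  if (any(df$copy_number < 0)) stop("copy_number must be non-negative")
  if (any(df$reliability < 0 | df$reliability > 100)) {
    stop("reliability must lie in [0,100]")
  }
  af_ok <- vapply(df$het_snp_afs, function(a) {
    length(a) == 0 || all(a >= 0 & a <= 1)
  }, logical(1))
  if (any(!af_ok)) stop("het_snp_afs values must lie in [0,1]")
  class(df) <- unique(c("cnv_segments", class(df)))
  df
}

#' Construct and validate a gene model table
#'
#' Gene bodies as 0-based half-open intervals with an optional cancer-gene
#' role used by the driver rules.
#'
#' @param df data.frame with columns `symbol`, `chrom`, `start`, `end` and
#'   optionally `role` (oncogene / tumour_suppressor / other / unknown).
#' @return Validated data.frame with class `"gene_models"`.
#' @export
gene_models <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("symbol", "chrom", "start", "end")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("gene model table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"role" %in% names(df)) df$role <- "unknown"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(!nzchar(df$symbol))) stop("gene symbols must be non-empty")
  if (any(df$start >= df$end)) stop("gene intervals must satisfy start < end")
  if (any(!df$role %in% .gene_roles)) {
    stop("role must be one of: ", paste(.gene_roles, collapse = ", "))
  }
  class(df) <- unique(c("gene_models", class(df)))
  df
}

#' Bundle a tumour sample
#'
#' @param id Sample identifier.
#' @param tumour_content Tumour purity, the fraction of cells in the
#'   specimen that are cancer cells; in `(0, 1]`.
#' @param variants A [variant_table()] of somatic SNVs/InDels.
#' @param segments A [cnv_segments()] table (may have zero rows).
#' @return A list with class `"tumour_sample"`.
#' @export
tumour_sample <- function(id, tumour_content, variants = variant_table(
                            empty_variant_table()),
                          segments = cnv_segments(empty_segment_table())) {
  if (!is.numeric(tumour_content) || length(tumour_content) != 1 ||
      tumour_content <= 0 || tumour_content > 1) {
    stop("tumour_content must be a single value in (0, 1]")
  }
  structure(list(id = id, tumour_content = tumour_content,
                 variants = variant_table(variants),
                 segments = cnv_segments(segments)),
            class = "tumour_sample")
}

#' Empty variant table skeleton
#' @return Zero-row data.frame with all variant columns.
#' @export
empty_variant_table <- function() {
  df <- data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   kind = character(0), effect = character(0),
                   gene = character(0), alt_reads = integer(0),
                   total_reads = integer(0), frac_plus = numeric(0),
                   frac_minus = numeric(0), stringsAsFactors = FALSE)
  for (col in c(.predictor_cols)) df[[col]] <- character(0)
  for (col in .maf_cols) df[[col]] <- numeric(0)
  df
}

#' Empty CNV segment table skeleton
#' @return Zero-row data.frame with all segment columns.
#' @export
empty_segment_table <- function() {
  df <- data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), copy_number = integer(0),
                   reliability = numeric(0), stringsAsFactors = FALSE)
  df$het_snp_afs <- list()
  df
}

#' Construct an expression matrix
#'
#' @param values Non-negative numeric matrix, genes in rows, samples in
#'   columns; dimnames required and unique.
#' @param unit `"scaled_estimate"` (per-sample values summing to ~1) or
#'   `"TPM"`.
#' @return The matrix with class `"expression_matrix"` and a `unit`
#'   attribute.
#' @export
expression_matrix <- function(values, unit = c("TPM", "scaled_estimate")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("gene and sample names must be unique")
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  structure(values, unit = unit, class = c("expression_matrix", "matrix"))
}
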