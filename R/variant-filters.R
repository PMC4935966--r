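# Somatic and germline variant filters: read-support and strand rules for
# tumour and matched-normal calls, replicate-round concordance, germline
# subtraction, and the rare-damaging-SNP chain (heterozygous/homozygous
# frequency windows, predictor consensus, population rarity, cross-cohort
# artifact removal). All thresholds default to the published values and
# are exposed as arguments.

.decision <- function(keys, failed) {
  data.frame(key = keys,
             passed = lengths(failed) == 0,
             failed_rules = vapply(failed, paste, character(1),
                                   collapse = ","),
             stringsAsFactors = FALSE)
}

.strand_ok <- function(variants, min_strand_frac) {
  pmin(variants$frac_plus, variants$frac_minus) >= min_strand_frac
}

#' Tumour-sample variant filters
#'
#' A tumour call passes when it is supported by at least `min_alt_reads`
#' mutated reads, has allele frequency at least `min_af`, and at least
#' `min_strand_frac` of its supporting reads map on each DNA strand.
#'
#' @param variants A [variant_table()].
#' @param min_alt_reads Minimum mutated reads (default 10).
#' @param min_af Minimum allele frequency (default 0.05).
#' @param min_strand_frac Minimum fraction of supporting reads per strand
#'   (default 0.01).
#' @return A decision data.frame: `key`, `passed`, `failed_rules`
#'   (comma-separated rule ids; empty iff passed).
#' @export
pass_tumour_filters <- function(variants, min_alt_reads = 10,
                                min_af = 0.05, min_strand_frac = 0.01) {
  f <- allele_frequency(variants)
  failed <- lapply(seq_len(nrow(variants)), function(i) {
    rules <- character(0)
    if (variants$alt_reads[i] < min_alt_reads) rules <- c(rules, "min_alt_reads")
    if (f[i] < min_af) rules <- c(rules, "min_af")
    if (!.strand_ok(variants[i, ], min_strand_frac)) rules <- c(rules, "strand_balance")
    rules
  })
  .decision(variant_key(variants), failed)
}

#' Matched-normal variant filters
#'
#' A normal-sample call passes with at least `min_alt_reads` (default 2)
#' mutated reads and the same per-strand support rule as tumour calls.
#'
#' @inheritParams pass_tumour_filters
#' @return A decision data.frame (see [pass_tumour_filters()]).
#' @export
pass_normal_filters <- function(variants, min_alt_reads = 2,
                                min_strand_frac = 0.01) {
  if (any(variants$total_reads == 0)) {
    stop("allele frequency undefined when total_reads is 0")
  }
  failed <- lapply(seq_len(nrow(variants)), function(i) {
    rules <- character(0)
    if (variants$alt_reads[i] < min_alt_reads) rules <- c(rules, "min_alt_reads")
    if (!.strand_ok(variants[i, ], min_strand_frac)) rules <- c(rules, "strand_balance")
    rules
  })
  .decision(variant_key(variants), failed)
}

#' Merge two independent sequencing rounds
#'
#' Tumour mode keeps only variants present in both rounds (replicate
#' concordance); normal mode keeps the union of the two rounds. Read
#' counts of the merged records are taken from `round1` (for union mode,
#' round2-only variants keep their own counts).
#'
#' @param round1,round2 [variant_table()]s from the same sample.
#' @param mode `"tumour"` (intersection) or `"normal"` (union).
#' @return A [variant_table()].
#' @export
merge_sequencing_rounds <- function(round1, round2,
                                    mode = c("tumour", "normal")) {
  mode <- match.arg(mode)
  k1 <- variant_key(round1)
  k2 <- variant_key(round2)
  if (mode == "tumour") {
    out <- round1[k1 %in% k2, , drop = FALSE]
  } else {
    out <- rbind(as.data.frame(round1),
                 as.data.frame(round2)[!k2 %in% k1, , drop = FALSE])
  }
  rownames(out) <- NULL
  variant_table(out)
}

#' Subtract germline calls from tumour calls
#'
#' Somatic variants are the tumour calls whose identity key is absent
#' from the matched-normal call set.
#'
#' @param tumour,normal [variant_table()]s.
#' @return A [variant_table()] of tumour-specific (somatic) variants.
#' @export
subtract_germline <- function(tumour, normal) {
  keep <- !variant_key(tumour) %in% variant_key(normal)
  out <- tumour[keep, , drop = FALSE]
  rownames(out) <- NULL
  variant_table(out)
}

#' Germline SNP filters
#'
#' A germline SNP passes with at least `min_alt_reads` mutated reads, the
#' per-strand support rule, and an allele frequency compatible with a
#' heterozygous (`[0.40, 0.60]`) or homozygous (`> 0.90`) genotype.
#'
#' @inheritParams pass_tumour_filters
#' @param het_window Inclusive heterozygous frequency window (default
#'   `c(0.40, 0.60)`).
#' @param hom_threshold Homozygous calls require `f > hom_threshold`
#'   (default 0.90).
#' @return A decision data.frame (see [pass_tumour_filters()]).
#' @export
pass_germline_snp_filters <- function(variants, min_alt_reads = 10,
                                      min_strand_frac = 0.01,
                                      het_window = c(0.40, 0.60),
                                      hom_threshold = 0.90) {
  f <- allele_frequency(variants)
  failed <- lapply(seq_len(nrow(variants)), function(i) {
    rules <- character(0)
    if (variants$alt_reads[i] < min_alt_reads) rules <- c(rules, "min_alt_reads")
    if (!.strand_ok(variants[i, ], min_strand_frac)) rules <- c(rules, "strand_balance")
    in_het <- f[i] >= het_window[1] && f[i] <= het_window[2]
    if (!in_het && !(f[i] > hom_threshold)) rules <- c(rules, "genotype_frequency")
    rules
  })
  .decision(variant_key(variants), failed)
}

#' Damaging-consequence rule
#'
#' All stopgain and stoploss variants are damaging. Nonsynonymous variants
#' are damaging when called so by at least `min_votes` of the five
#' predictors (SIFT, PolyPhen2, MutationTaster, MutationAssessor, LRT).
#' By default a missing predictor call counts as a non-damaging vote and
#' the denominator stays at five; `missing_as_abstention = TRUE` instead
#' drops missing predictors from the denominator (and scales the required
#' majority to `min_votes / 5` of the available calls).
#'
#' @param variants A [variant_table()].
#' @param min_votes Damaging votes required out of five (default 4).
#' @param missing_as_abstention Treat missing calls as abstentions with a
#'   reduced denominator (default `FALSE`).
#' @return Logical vector, one per variant.
#' @export
is_damaging <- function(variants, min_votes = 4,
                        missing_as_abstention = FALSE) {
  calls <- as.matrix(as.data.frame(variants)[, .predictor_cols, drop = FALSE])
  damaging_votes <- rowSums(calls == "damaging", na.rm = TRUE)
  available <- rowSums(!is.na(calls))
  truncating <- variants$effect %in% c("stopgain", "stoploss")
  if (missing_as_abstention) {
    need <- ceiling(min_votes / 5 * pmax(available, 1))
    consensus <- available > 0 & damaging_votes >= need
  } else {
    consensus <- damaging_votes >= min_votes
  }
  truncating | (variants$effect == "nonsynonymous" & consensus)
}

#' Population rarity rule
#'
#' A variant is rare when every available population panel reports a
#' minor allele frequency below `threshold`; a variant absent from all
#' panels (both MAFs missing) is rare.
#'
#' @param variants A [variant_table()].
#' @param threshold MAF threshold (default 0.01).
#' @return Logical vector, one per variant.
#' @export
is_rare <- function(variants, threshold = 0.01) {
  mafs <- as.matrix(as.data.frame(variants)[, .maf_cols, drop = FALSE])
  apply(mafs, 1, function(m) all(is.na(m) | m < threshold))
}

#' Cross-cohort artifact filter
#'
#' Variant keys never observed in the population panels but carried by
#' more than `max_carrier_frac` of samples are removed as likely
#' alignment/sequencing artifacts. `mode = "pooled"` (default) evaluates
#' the carrier fraction over all samples pooled across cohorts;
#' `mode = "per_cohort"` removes a key only when it exceeds the fraction
#' in every cohort.
#'
#' @param cohorts Named list of cohorts; each cohort is a list of
#'   per-sample character vectors of variant keys.
#' @param panel_presence Named logical vector: `TRUE` if the key is
#'   observed in any population panel.
#' @param max_carrier_frac Removal requires carrier fraction strictly
#'   greater than this (default 0.5).
#' @param mode `"pooled"` or `"per_cohort"`.
#' @return Character vector of retained keys.
#' @export
cohort_artifact_filter <- function(cohorts, panel_presence,
                                   max_carrier_frac = 0.5,
                                   mode = c("pooled", "per_cohort")) {
  mode <- match.arg(mode)
  if (length(cohorts) == 0 || any(lengths(cohorts) == 0)) {
    stop("each cohort must contain at least one sample")
  }
  all_keys <- unique(unlist(cohorts, use.names = FALSE))
  carrier_frac <- function(samples, key) {
    mean(vapply(samples, function(s) key %in% s, logical(1)))
  }
  removed <- vapply(all_keys, function(k) {
    if (k %in% names(panel_presence) && isTRUE(panel_presence[[k]])) {
      return(FALSE)
    }
    if (mode == "pooled") {
      pooled <- unlist(cohorts, recursive = FALSE, use.names = FALSE)
      carrier_frac(pooled, k) > max_carrier_frac
    } else {
      all(vapply(cohorts, carrier_frac, numeric(1), key = k) >
            max_carrier_frac)
    }
  }, logical(1))
  all_keys[!removed]
}

#' Rare damaging SNP chain for one sample
#'
#' Convenience composition of the germline filters: SNPs that pass the
#' read-support/genotype filters, are damaging by [is_damaging()] and
#' rare by [is_rare()].
#'
#' @param variants A [variant_table()] of germline calls.
#' @param ... Passed on to the individual rules.
#' @return The qualifying subset, as a [variant_table()].
#' @export
rare_damaging_snps <- function(variants, ...) {
  keep <- pass_germline_snp_filters(variants)$passed &
    is_damaging(variants) & is_rare(variants)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  variant_table(out)
}
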