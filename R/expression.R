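# Expression-class gene-set enrichment. Per sample, genes fall into four
# classes from the sample's own TPM distribution: not expressed
# (TPM < 0.1, takes precedence), highly expressed (above the 75th
# percentile), lowly expressed (below the 25th percentile) and medium
# otherwise. Cohorts are compared per gene set and class with Fisher's
# exact test on pooled (gene, sample) pairs, BH-corrected across sets,
# with a down-sampling bootstrap for unbalanced cohorts.

.expression_classes <- c("not_expressed", "low", "medium", "high")

#' Convert scaled-estimate values to TPM
#'
#' Scaled estimates are per-sample transcript fractions (columns summing
#' to ~1); TPM multiplies them by one million.
#'
#' @param m An [expression_matrix()] with unit `"scaled_estimate"`.
#' @return An [expression_matrix()] in TPM.
#' @export
tpm_from_scaled_estimates <- function(m) {
  if (!identical(attr(m, "unit"), "scaled_estimate")) {
    stop("input must carry unit 'scaled_estimate'")
  }
  if (any(m < 0)) stop("expression values must be non-negative")
  expression_matrix(unclass(m) * 1e6, unit = "TPM")
}

#' Expression classes for one sample
#'
#' Percentiles are computed over the sample's full TPM distribution
#' (linear-interpolation quantiles), including genes later labelled not
#' expressed; the `TPM < not_expressed_cutoff` rule then takes
#' precedence. `high` requires TPM strictly above the 75th percentile,
#' `low` strictly below the 25th; everything else is `medium`.
#'
#' @param tpms Named numeric vector of per-gene TPMs for one sample
#'   (at least 4 genes).
#' @param not_expressed_cutoff TPM threshold (default 0.1).
#' @return Character vector of class labels, named by gene.
#' @export
classify_expression_sample <- function(tpms, not_expressed_cutoff = 0.1) {
  if (length(tpms) < 4) stop("need at least 4 genes")
  q <- stats::quantile(tpms, c(0.25, 0.75), names = FALSE, type = 7)
  labels <- rep("medium", length(tpms))
  labels[tpms > q[2]] <- "high"
  labels[tpms < q[1]] <- "low"
  labels[tpms < not_expressed_cutoff] <- "not_expressed"
  names(labels) <- names(tpms)
  labels
}

#' Expression classes for every sample of a matrix
#'
#' @param m An [expression_matrix()] in TPM.
#' @param ... Passed to [classify_expression_sample()].
#' @return Character matrix of labels, same dimnames as `m`.
#' @export
classify_expression_matrix <- function(m, ...) {
  if (!identical(attr(m, "unit"), "TPM")) stop("matrix must be in TPM")
  out <- apply(unclass(m), 2, classify_expression_sample, ...)
  rownames(out) <- rownames(m)
  out
}

#' Class-fraction comparison for one gene set
#'
#' Pools (gene, sample) pairs over the set's genes in each cohort and
#' compares the in-class fraction with Fisher's exact test (two-sided)
#' on the 2x2 table rows = cohorts, columns = in-class vs not.
#' `per_sample_mean` mode is available for sensitivity analyses: it
#' compares per-sample in-class fractions with the one-tailed rank-sum
#' test instead of pooling pairs.
#'
#' @param set Character vector of member gene symbols.
#' @param labels_a,labels_b Gene-by-sample label matrices (from
#'   [classify_expression_matrix()]) over the same gene universe.
#' @param class One of `not_expressed`, `low`, `medium`, `high`.
#' @param mode `"pooled"` (default) or `"per_sample_mean"`.
#' @return List with `set_size`, `table` (2x2 counts, pooled mode),
#'   `p_value`.
#' @export
class_fraction_test <- function(set, labels_a, labels_b, class,
                                mode = c("pooled", "per_sample_mean")) {
  mode <- match.arg(mode)
  class <- match.arg(class, .expression_classes)
  members <- intersect(unique(set), rownames(labels_a))
  if (length(members) == 0) stop("gene set has no genes in the universe")
  la <- labels_a[members, , drop = FALSE]
  lb <- labels_b[members, , drop = FALSE]
  if (mode == "pooled") {
    in_a <- sum(la == class)
    in_b <- sum(lb == class)
    tab <- matrix(c(in_a, length(la) - in_a,
                    in_b, length(lb) - in_b),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("in_class", "other")))
    list(set_size = length(members), table = tab,
         p_value = fisher_exact_2x2(tab)$p_value)
  } else {
    fa <- colMeans(la == class)
    fb <- colMeans(lb == class)
    list(set_size = length(members), table = NULL,
         p_value = wilcoxon_rank_sum_one_tailed(fa, fb)$p_value)
  }
}

#' Class-fraction scan over gene sets
#'
#' Runs [class_fraction_test()] for every set and BH-corrects across
#' sets (within the chosen class).
#'
#' @param sets Named list of gene sets.
#' @param labels_a,labels_b As in [class_fraction_test()].
#' @param class Expression class to compare.
#' @param ... Passed to [class_fraction_test()].
#' @return data.frame with `set`, `set_size`, `p`, `q`.
#' @export
class_enrichment_scan <- function(sets, labels_a, labels_b, class, ...) {
  if (length(sets) == 0) stop("need at least one gene set")
  rows <- lapply(names(sets), function(nm) {
    r <- class_fraction_test(sets[[nm]], labels_a, labels_b, class, ...)
    data.frame(set = nm, set_size = r$set_size, p = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Down-sampling bootstrap for unbalanced expression cohorts
#'
#' Repeatedly selects `ncol(labels_a)` samples from the larger cohort B
#' (without replacement within an iteration), recomputes the class
#' fraction comparison against the fixed cohort A, and reports the
#' proportion of iterations with `p < alpha`.
#'
#' @param set Character vector of member gene symbols.
#' @param labels_a Label matrix of the smaller cohort.
#' @param labels_b Label matrix of the larger cohort
#'   (`ncol(labels_b) > ncol(labels_a)`).
#' @param class Expression class to compare.
#' @param n_iter Iterations (default 10000).
#' @param alpha Per-iteration significance level (default 0.05).
#' @param seed Integer seed for reproducibility.
#' @return Proportion of significant comparisons.
#' @export
expression_bootstrap <- function(set, labels_a, labels_b, class,
                                 n_iter = 10000, alpha = 0.05,
                                 seed = NULL) {
  n_a <- ncol(labels_a)
  n_b <- ncol(labels_b)
  if (n_b <= n_a) stop("cohort B must be larger than cohort A")
  if (n_iter < 1) stop("n_iter must be at least 1")
  .with_seed(seed, function() {
    hits <- vapply(seq_len(n_iter), function(i) {
      sub <- labels_b[, sample.int(n_b, n_a, replace = FALSE), drop = FALSE]
      class_fraction_test(set, labels_a, sub, class)$p_value < alpha
    }, logical(1))
    mean(hits)
  })
}
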