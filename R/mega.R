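# MEGA: mutation enrichment gene set analysis. For a gene set X and two
# cohorts, the per-sample burden is the number of mutations falling in
# genes of X; the burden distributions D_A and D_B are compared with the
# one-tailed Wilcoxon rank-sum test (is cohort A enriched?), corrected
# across sets by Benjamini-Hochberg. Unbalanced cohorts are handled by a
# down-sampling bootstrap: the larger cohort is resampled (with
# replacement) to the smaller cohort's size many times and the fraction
# of significant comparisons reported.

#' Per-sample mutation burden within a gene set
#'
#' @param set Character vector of member gene symbols.
#' @param profile Named integer vector of per-gene mutation counts for
#'   one sample; genes absent from the profile contribute 0.
#' @return Total count over the (de-duplicated) set members.
#' @export
geneset_burden <- function(set, profile) {
  set <- unique(set)
  sum(profile[names(profile) %in% set])
}

#' Burden distribution of a cohort
#'
#' @param set Character vector of member gene symbols.
#' @param profiles Gene-by-sample count matrix (rownames = genes), or a
#'   list of named per-sample count vectors.
#' @return Numeric vector of per-sample burdens.
#' @export
cohort_burdens <- function(set, profiles) {
  set <- unique(set)
  if (is.matrix(profiles)) {
    rows <- rownames(profiles) %in% set
    colSums(profiles[rows, , drop = FALSE])
  } else {
    vapply(profiles, geneset_burden, numeric(1), set = set)
  }
}

#' MEGA test for one gene set
#'
#' Builds the burden distributions of both cohorts and tests whether
#' cohort A carries more mutations in the set than cohort B (one-tailed
#' Wilcoxon rank-sum).
#'
#' @param set Character vector of member gene symbols.
#' @param cohort_a,cohort_b Gene-by-sample count matrices (or lists of
#'   named vectors); both non-empty.
#' @return P-value.
#' @export
mega_test <- function(set, cohort_a, cohort_b) {
  da <- cohort_burdens(set, cohort_a)
  db <- cohort_burdens(set, cohort_b)
  if (length(da) == 0 || length(db) == 0) stop("cohorts must be non-empty")
  wilcoxon_rank_sum_one_tailed(da, db)$p_value
}

#' MEGA scan over a collection of gene sets
#'
#' Runs [mega_test()] for every set and corrects the p-values for FDR
#' across all sets.
#'
#' @param sets Named list of gene sets (e.g. from [read_gene_sets()]).
#' @param cohort_a,cohort_b As in [mega_test()].
#' @return data.frame with `set`, `n_a`, `n_b`, `median_a`, `median_b`,
#'   `p`, `q`, in the input set order.
#' @export
mega_scan <- function(sets, cohort_a, cohort_b) {
  if (length(sets) == 0) stop("need at least one gene set")
  rows <- lapply(names(sets), function(nm) {
    da <- cohort_burdens(sets[[nm]], cohort_a)
    db <- cohort_burdens(sets[[nm]], cohort_b)
    data.frame(set = nm, n_a = length(da), n_b = length(db),
               median_a = stats::median(da), median_b = stats::median(db),
               p = wilcoxon_rank_sum_one_tailed(da, db)$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' MEGA down-sampling bootstrap for unbalanced cohorts
#'
#' The larger cohort is down-sampled (random sampling with replacement)
#' to the size of the smaller cohort `n_iter` times; the smaller cohort
#' is held fixed. Each iteration repeats the one-tailed rank-sum
#' comparison, and the proportion of significant iterations
#' (`p < alpha`) is returned. With equal cohort sizes the bootstrap
#' degenerates to the indicator of the single comparison being
#' significant.
#'
#' @param set Character vector of member gene symbols.
#' @param cohort_a,cohort_b As in [mega_test()].
#' @param n_iter Number of bootstrap iterations (default 10000).
#' @param alpha Per-iteration significance level (default 0.05).
#' @param seed Integer seed; identical seeds give identical proportions.
#' @return Proportion of significant comparisons in `[0, 1]`.
#' @export
mega_bootstrap <- function(set, cohort_a, cohort_b, n_iter = 10000,
                           alpha = 0.05, seed = NULL) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  da <- cohort_burdens(set, cohort_a)
  db <- cohort_burdens(set, cohort_b)
  if (length(da) == length(db)) {
    return(as.numeric(wilcoxon_rank_sum_one_tailed(da, db)$p_value < alpha))
  }
  a_larger <- length(da) > length(db)
  big <- if (a_larger) da else db
  small <- if (a_larger) db else da
  .with_seed(seed, function() {
    hits <- vapply(seq_len(n_iter), function(i) {
      sub <- big[sample.int(length(big), length(small), replace = TRUE)]
      p <- if (a_larger) {
        wilcoxon_rank_sum_one_tailed(sub, small)$p_value
      } else {
        wilcoxon_rank_sum_one_tailed(small, sub)$p_value
      }
      p < alpha
    }, logical(1))
    mean(hits)
  })
}

#' Build per-sample mutation profiles from a variant table
#'
#' Counts qualifying variants per gene per sample (one variant = one
#' mutation). Typically applied to the output of [rare_damaging_snps()].
#'
#' @param variants_by_sample Named list of [variant_table()]s, one per
#'   sample.
#' @param genes Optional gene universe (rownames of the output); default
#'   is the union of observed genes.
#' @return Gene-by-sample integer count matrix.
#' @export
mutation_profiles <- function(variants_by_sample, genes = NULL) {
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(variants_by_sample,
                                       function(v) v$gene))))
  }
  m <- matrix(0L, nrow = length(genes), ncol = length(variants_by_sample),
              dimnames = list(genes, names(variants_by_sample)))
  for (j in seq_along(variants_by_sample)) {
    tab <- table(variants_by_sample[[j]]$gene)
    hit <- intersect(names(tab), genes)
    m[hit, j] <- as.integer(tab[hit])
  }
  m
}
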