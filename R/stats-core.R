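# Statistical primitives shared by MEGA and the expression module, with
# the exact/approximate policy pinned down: the rank-sum test enumerates
# the exact null for small tie-free inputs and otherwise uses the normal
# approximation with tie and continuity corrections.

.test_result <- function(statistic, p_value, method, alternative) {
  structure(list(statistic = unname(statistic),
                 p_value = min(max(p_value, 0), 1),
                 method = method, alternative = alternative),
            class = "test_result")
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Tests whether `a` is stochastically greater than `b`. When the
#' combined sample size is at most `exact_limit`, the exact permutation
#' null of the rank-sum statistic is enumerated (midranks handle tied
#' values, so small tied samples are still exact; on tie-free data this
#' reproduces the classical exact distribution). Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_limit Combined-size threshold for the exact branch
#'   (default 20).
#' @return A `test_result` list: `statistic` (Mann-Whitney U), `p_value`,
#'   `method`, `alternative`.
#' @export
wilcoxon_rank_sum_one_tailed <- function(a, b, exact_limit = 20) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  n <- length(a)
  m <- length(b)
  if (n + m <= exact_limit) {
    r <- rank(c(a, b))
    obs <- sum(r[seq_len(n)])
    combs <- utils::combn(n + m, n)
    null_sums <- colSums(matrix(r[combs], nrow = n))
    p <- mean(null_sums >= obs - 1e-9)
    u <- obs - n * (n + 1) / 2
    .test_result(u, p, method = "wilcoxon_exact", alternative = "greater")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      a, b, alternative = "greater", exact = FALSE, correct = TRUE))
    .test_result(wt$statistic, wt$p.value,
                 method = "wilcoxon_normal_approx",
                 alternative = "greater")
  }
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric p-value; the two-sided p sums the probabilities
#' of all tables (with the observed margins) no more probable than the
#' observed one.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param alternative `"two_sided"` (default) or `"greater"` (odds ratio
#'   of the first row above 1).
#' @return A `test_result` list (`statistic` is the sample odds ratio
#'   estimate, `NA` for degenerate margins).
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (sum(table) == 0) stop("at least one count must be positive")
  ft <- stats::fisher.test(table, alternative = switch(alternative,
                                                       two_sided = "two.sided",
                                                       greater = "greater"))
  .test_result(unname(ft$estimate), ft$p.value, method = "fisher_exact",
               alternative = alternative)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `q_(i) = min_{j >= i} ( p_(j) * m / j )`, capped at
#' 1; monotone in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Run a function with a temporary RNG state seeded from `seed`, restoring
# the caller's stream afterwards so seeded helpers do not perturb global
# reproducibility.
.with_seed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

# Named substream: derive a stable 31-bit seed from the master seed and a
# stream label, so adding one generator never perturbs the draws of
# another.
.substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}
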