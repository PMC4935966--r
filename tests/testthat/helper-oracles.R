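# Independent brute-force oracles used to verify the package's
# statistical primitives and interval arithmetic. These stay deliberately
# naive (full enumeration, per-base counting) and never call the code
# paths they check.

# Exact one-tailed rank-sum p-value by enumerating every assignment of
# ranks to group A: p = P(rank-sum >= observed) under the permutation
# null. Tie-free data only.
enum_wilcoxon_greater <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  null_sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(null_sums >= obs)
}

# Fisher p-values by enumerating every table with the observed margins
# under the hypergeometric null.
enum_fisher <- function(tab, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  if (alternative == "greater") {
    sum(probs[support >= tab[1, 1]])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

# Benjamini-Hochberg step-up from the definition.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Per-base overlap fraction of a gene with a union of regions (all
# 0-based half-open, integer coordinates).
brute_force_overlap <- function(gene_start, gene_end, region_starts,
                                region_ends) {
  bases <- gene_start:(gene_end - 1)
  covered <- vapply(bases, function(b) {
    any(region_starts <= b & b < region_ends)
  }, logical(1))
  mean(covered)
}

# Small valid variant table for filter tests; fields overridable.
make_variants <- function(n = 1, ...) {
  df <- data.frame(
    chrom = rep("chr1", n), pos = seq_len(n) * 100L,
    ref = rep("A", n), alt = rep("G", n),
    kind = rep("SNV", n), effect = rep("nonsynonymous", n),
    gene = sprintf("GENE%d", seq_len(n)),
    alt_reads = rep(20L, n), total_reads = rep(100L, n),
    frac_plus = rep(0.5, n), frac_minus = rep(0.5, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  variant_table(df)
}

make_segments <- function(chrom = "chr1", start = 0L, end = 1000L,
                          copy_number = 3L, reliability = 99,
                          het_snp_afs = list(numeric(0))) {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   copy_number = copy_number, reliability = reliability,
                   stringsAsFactors = FALSE)
  df$het_snp_afs <- het_snp_afs
  cnv_segments(df)
}
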