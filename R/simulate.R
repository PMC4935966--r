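# Synthetic-data generators with known ground truth. The read model is
# the standard exome noise model: per-site total depth ~ Poisson(depth),
# mutated reads ~ Binomial(total, expected VAF). For a heterozygous
# diploid mutation carried by a clone of cellular prevalence c in a
# specimen of purity tc, the expected raw VAF is c * tc / 2 — the exact
# inverse of the clonality estimator, so recovery can be scored against
# the generating truth. One master seed drives named substreams per
# generator, so adding a generator never perturbs another's draws.

#' Specify a tumour clone
#'
#' @param prevalence Cellular prevalence (fraction of cancer cells in the
#'   clone), in `(0, 1]`.
#' @param n_mutations Number of mutations private to the clone.
#' @return A `clone_spec` list.
#' @export
clone_spec <- function(prevalence, n_mutations) {
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must lie in (0, 1]")
  if (n_mutations < 0) stop("n_mutations must be non-negative")
  structure(list(prevalence = prevalence, n_mutations = n_mutations),
            class = "clone_spec")
}

#' Simulate a multi-clone tumour sample
#'
#' For every mutation of every clone, total reads are drawn
#' Poisson(`depth`) (zero draws replaced by 1 so the frequency is
#' defined), mutated reads Binomial(total, `prevalence * tc / 2`), and
#' plus-strand supporting reads Binomial(alt, 0.5). All mutations are
#' nonsynonymous SNVs on synthetic coordinates; the generating clone of
#' each mutation is recorded in the `truth` attribute.
#'
#' @param clones List of [clone_spec()]s.
#' @param tc Tumour content (purity) in `(0, 1]`.
#' @param depth Mean sequencing depth (>= 1).
#' @param seed Integer seed.
#' @param id Sample identifier.
#' @return A [tumour_sample()]; `attr(x, "truth")` holds the per-mutation
#'   clone prevalences.
#' @export
simulate_tumour <- function(clones, tc, depth, seed = NULL,
                            id = "synthetic_tumour") {
  if (tc <= 0 || tc > 1) stop("tc must lie in (0, 1]")
  if (depth < 1) stop("depth must be at least 1")
  if (inherits(clones, "clone_spec")) clones <- list(clones)
  seed <- if (is.null(seed)) NULL else .substream_seed(seed, "tumour")
  .with_seed(seed, function() {
    prevalence <- unlist(lapply(clones, function(cl) {
      rep(cl$prevalence, cl$n_mutations)
    }))
    n <- length(prevalence)
    if (n == 0) stop("no mutations to simulate")
    total <- pmax(stats::rpois(n, depth), 1L)
    alt <- stats::rbinom(n, total, prevalence * tc / 2)
    plus <- stats::rbinom(n, alt, 0.5)
    frac_plus <- ifelse(alt > 0, plus / alt, 0.5)
    df <- data.frame(
      chrom = "chr1", pos = seq_len(n) * 1000L,
      ref = "A", alt = "T", kind = "SNV", effect = "nonsynonymous",
      gene = sprintf("G%05d", seq_len(n)),
      alt_reads = alt, total_reads = total,
      frac_plus = frac_plus, frac_minus = 1 - frac_plus,
      stringsAsFactors = FALSE)
    out <- tumour_sample(id = id, tumour_content = tc,
                         variants = variant_table(df))
    attr(out, "truth") <- data.frame(id = variant_key(df),
                                     clone_prevalence = prevalence)
    out
  })
}

#' Simulate a CNV segment with allelic imbalance in het SNPs
#'
#' The expected tumour allele frequency of each heterozygous SNP mixes
#' three cell populations by their fractions: normal cells (`1 - tc`, AF
#' 0.5), unaffected cancer cells (`tc * (1 - c)`, AF 0.5) and affected
#' cancer cells (`tc * c`) whose allele ratio follows the copy number
#' under a single-allele change (e.g. 2/3 for CN = 3, 1 for the retained
#' allele of CN = 1). Each SNP's B allele lands on the affected homologue
#' with probability 0.5, so AFs scatter on both sides of 0.5. Reads are
#' sampled binomially at Poisson(`depth`) coverage.
#'
#' @param copy_number Integer copy number of the aberrant region
#'   (not 2: a balanced region has no imbalance to simulate).
#' @param clonality Fraction of cancer cells carrying the aberration.
#' @param tc Tumour content in `(0, 1]`.
#' @param n_snps Number of het SNPs in the region (>= 1).
#' @param depth Mean coverage (>= 1).
#' @param seed Integer seed.
#' @param chrom,start,end Segment coordinates (0-based half-open).
#' @param reliability Reliability score to record (default 99).
#' @return One-row [cnv_segments()] table; `attr(x, "truth")` records the
#'   generating clonality and expected allele frequencies.
#' @export
simulate_cnv_segment <- function(copy_number, clonality, tc, n_snps,
                                 depth, seed = NULL, chrom = "chr1",
                                 start = 0L, end = 1000000L,
                                 reliability = 99) {
  if (copy_number == 2 && clonality > 0) {
    stop("CN=2 carries no allelic imbalance to simulate")
  }
  if (tc <= 0 || tc > 1) stop("tc must lie in (0, 1]")
  if (clonality < 0 || clonality > 1) stop("clonality must lie in [0, 1]")
  if (n_snps < 1) stop("n_snps must be at least 1")
  seed <- if (is.null(seed)) NULL else .substream_seed(seed, "cnv")
  .with_seed(seed, function() {
    # B-allele copies / total copies in affected cells, single-allele change
    b_on_affected <- stats::runif(n_snps) < 0.5
    if (copy_number > 2) {
      gained <- copy_number - 1   # copies of the changed homologue
      ratio_hi <- gained / copy_number
    } else if (copy_number == 1) {
      ratio_hi <- 1               # retained homologue
    } else if (copy_number == 0) {
      ratio_hi <- 0.5             # both lost; remaining cells stay balanced
    } else {
      ratio_hi <- 0.5
    }
    af_affected <- ifelse(b_on_affected, ratio_hi, 1 - ratio_hi)
    w_aff <- tc * clonality
    expected_af <- (1 - w_aff) * 0.5 + w_aff * af_affected
    cov <- pmax(stats::rpois(n_snps, depth), 1L)
    b_reads <- stats::rbinom(n_snps, cov, expected_af)
    afs <- b_reads / cov
    seg <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end),
                      copy_number = as.integer(copy_number),
                      reliability = reliability,
                      stringsAsFactors = FALSE)
    seg$het_snp_afs <- list(afs)
    out <- cnv_segments(seg)
    attr(out, "truth") <- list(clonality = clonality,
                               expected_af = expected_af)
    out
  })
}

#' Simulate two cohorts of per-sample gene mutation counts
#'
#' Per-sample per-gene counts are Poisson with a background rate; genes
#' belonging to enriched sets have their rate multiplied in cohort A
#' only. With `multiplier = 1` the cohorts are exchangeable.
#'
#' @param n_a,n_b Cohort sizes.
#' @param genes Character vector: the gene universe.
#' @param sets Named list of gene sets (subsets of `genes`).
#' @param background_rate Per-gene Poisson rate (default 0.005).
#' @param enriched_sets Names of sets enriched in cohort A.
#' @param multiplier Rate multiplier for enriched-set genes in cohort A
#'   (>= 1, default 1).
#' @param seed Integer seed.
#' @return List with gene-by-sample count matrices `cohort_a`,
#'   `cohort_b`, and `truth` (the enriched set names).
#' @export
simulate_mega_cohorts <- function(n_a, n_b, genes, sets,
                                  background_rate = 0.005,
                                  enriched_sets = character(0),
                                  multiplier = 1, seed = NULL) {
  if (background_rate < 0) stop("background_rate must be non-negative")
  if (multiplier < 1) stop("multiplier must be at least 1")
  stopifnot(all(enriched_sets %in% names(sets)))
  seed <- if (is.null(seed)) NULL else .substream_seed(seed, "mega")
  .with_seed(seed, function() {
    rate_a <- rep(background_rate, length(genes))
    names(rate_a) <- genes
    enriched_genes <- unique(unlist(sets[enriched_sets]))
    rate_a[genes %in% enriched_genes] <- background_rate * multiplier
    draw <- function(rates, n) {
      m <- matrix(stats::rpois(length(rates) * n, rates),
                  nrow = length(rates), ncol = n,
                  dimnames = list(genes, sprintf("S%03d", seq_len(n))))
      m
    }
    list(cohort_a = draw(rate_a, n_a),
         cohort_b = draw(rep(background_rate, length(genes)), n_b),
         truth = list(enriched_sets = enriched_sets))
  })
}

#' Simulate expression cohorts with suppressed gene sets
#'
#' Baseline TPMs are log-normal (meanlog 3, sdlog 2 by default — a
#' realistic bulk RNA-seq spread with a few percent of genes under the
#' 0.1 TPM detection floor). In cohort A, a chosen fraction of each
#' suppressed set's genes is forced below 0.1 TPM in every sample.
#'
#' @param n_a,n_b Cohort sizes.
#' @param genes Character vector: the gene universe.
#' @param suppressed_sets Named list of gene sets to suppress in cohort A.
#' @param suppression_fraction Fraction of each suppressed set's genes
#'   forced below 0.1 TPM in cohort A, in `[0, 1]`.
#' @param meanlog,sdlog Baseline log-normal parameters.
#' @param seed Integer seed.
#' @return List with [expression_matrix()]s `cohort_a`, `cohort_b` (TPM)
#'   and `truth` (the suppressed gene symbols).
#' @export
simulate_expression_cohorts <- function(n_a, n_b, genes,
                                        suppressed_sets = list(),
                                        suppression_fraction = 0,
                                        meanlog = 3, sdlog = 2,
                                        seed = NULL) {
  if (suppression_fraction < 0 || suppression_fraction > 1) {
    stop("suppression_fraction must lie in [0, 1]")
  }
  seed <- if (is.null(seed)) NULL else .substream_seed(seed, "expression")
  .with_seed(seed, function() {
    g <- length(genes)
    draw <- function(n, prefix) {
      m <- matrix(stats::rlnorm(g * n, meanlog, sdlog), nrow = g, ncol = n,
                  dimnames = list(genes, sprintf("%s%03d", prefix,
                                                 seq_len(n))))
      m
    }
    a <- draw(n_a, "A")
    b <- draw(n_b, "B")
    suppressed_genes <- character(0)
    for (set in suppressed_sets) {
      members <- intersect(set, genes)
      k <- round(suppression_fraction * length(members))
      if (k > 0) {
        pick <- sample(members, k)
        # silenced: uniform below the detection floor, all cohort-A samples
        a[pick, ] <- stats::runif(length(pick) * n_a, 0, 0.1)
        suppressed_genes <- c(suppressed_genes, pick)
      }
    }
    list(cohort_a = expression_matrix(a, unit = "TPM"),
         cohort_b = expression_matrix(b, unit = "TPM"),
         truth = list(suppressed_genes = unique(suppressed_genes)))
  })
}

#' Simulate a cohort of tumours with known clone composition
#'
#' Convenience wrapper over [simulate_tumour()] reproducing the three
#' canonical architectures: monoclonal (one clone at prevalence 1),
#' biclonal (truncal clone at 1 plus a prevalent subclone at 0.5, which
#' carries the majority of private mutations) and polyclonal (three
#' minor clones at 0.25 / 0.20 / 0.15).
#'
#' @param class `"monoclonal"`, `"biclonal"` or `"polyclonal"`.
#' @param tc Tumour content.
#' @param depth Mean depth.
#' @param n_mutations Total mutations (default 150).
#' @param seed Integer seed.
#' @return A [tumour_sample()] (see [simulate_tumour()]).
#' @export
simulate_tumour_class <- function(class = c("monoclonal", "biclonal",
                                            "polyclonal"),
                                  tc, depth, n_mutations = 150,
                                  seed = NULL) {
  class <- match.arg(class)
  clones <- switch(class,
    monoclonal = list(clone_spec(1.0, n_mutations)),
    biclonal = list(clone_spec(1.0, round(n_mutations / 3)),
                    clone_spec(0.5, n_mutations - round(n_mutations / 3))),
    polyclonal = {
      k <- round(n_mutations / 3)
      list(clone_spec(0.25, k), clone_spec(0.20, k),
           clone_spec(0.15, n_mutations - 2 * k))
    })
  out <- simulate_tumour(clones, tc = tc, depth = depth, seed = seed,
                         id = paste0("synthetic_", class))
  attr(out, "truth_class") <- class
  out
}
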