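# Reconstruction of tumour clone composition. The clonality of an
# alteration is the fraction of cancer cells that carry it. For a
# heterozygous diploid mutation observed at raw allele frequency f in a
# specimen of tumour content tc, the purity-corrected frequency is
# f' = f / tc and the clonality c = 2 f' (two alleles per cell), with a
# two-allele treatment in the almost-clonal regime f' > 0.5. CNV-region
# clonality comes from the deviation of the median heterozygous-SNP
# allele frequency from the balanced 50%.

#' Mutations usable for clonality (diploid regions only)
#'
#' Amplifications and deletions distort allele frequencies, so only
#' SNVs/InDels falling outside every high-confidence aberrant region are
#' used for mutation clonality.
#'
#' @param sample A [tumour_sample()].
#' @param ... Passed to [is_high_confidence_region()].
#' @return A [variant_table()] subset.
#' @export
select_diploid_mutations <- function(sample, ...) {
  variants <- sample$variants
  segs <- sample$segments
  if (nrow(segs) > 0) {
    hc <- segs[is_high_confidence_region(segs, ...), , drop = FALSE]
    if (nrow(hc) > 0) {
      inside <- vapply(seq_len(nrow(variants)), function(i) {
        any(hc$chrom == variants$chrom[i] &
              hc$start < variants$pos[i] & variants$pos[i] <= hc$end)
      }, logical(1))
      variants <- variants[!inside, , drop = FALSE]
    }
  }
  rownames(variants) <- NULL
  variant_table(variants)
}

#' Tumour-content correction of an allele frequency
#'
#' Removes the wild-type allele contribution of admixed normal cells:
#' `f' = min(f / tc, 1)`. Identity at `tc = 1`; monotone non-decreasing
#' in `f`.
#'
#' @param f Raw allele frequency (or vector), in `[0, 1]`.
#' @param tc Tumour content (purity) in `(0, 1]`.
#' @return Corrected frequency `f'` in `[0, 1]`.
#' @export
correct_allele_frequency <- function(f, tc) {
  if (length(tc) != 1 || tc <= 0 || tc > 1) stop("tc must lie in (0, 1]")
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  pmin(f / tc, 1)
}

#' Clonality of a mutation from its corrected allele frequency
#'
#' For `f' <= 0.5` the mutation sits on one allele of a fraction
#' `c = 2 f'` of cancer cells. For `0.5 < f' <= 1` (almost clonal) the
#' excess frequency is attributed to a second mutated allele in a subset
#' of cells: allele clonalities `c1 = 1` and `c2 = 2 f' - 1`, with the
#' cell-level clonality `c = min(2 f', 1) = 1` (every cancer cell carries
#' at least one mutated allele). Continuous and non-decreasing in `f'`,
#' with `c(0.5) = 1`.
#'
#' @param f_corrected Corrected allele frequency (vector ok), `[0, 1]`.
#' @return data.frame with `c`, `c_allele1`, `c_allele2` (allele
#'   clonalities are `NA` outside the almost-clonal regime).
#' @export
mutation_clonality <- function(f_corrected) {
  if (any(f_corrected < 0 | f_corrected > 1)) {
    stop("corrected allele frequency must lie in [0, 1]")
  }
  c_val <- pmin(2 * f_corrected, 1)
  almost <- f_corrected > 0.5
  data.frame(c = c_val,
             c_allele1 = ifelse(almost, 1, NA_real_),
             c_allele2 = ifelse(almost, 2 * f_corrected - 1, NA_real_))
}

#' Median heterozygous-SNP allele frequency of a CNV region
#'
#' Heterozygous SNPs (40-60% allele frequency in the matched normal)
#' deviate from 50% in the tumour when the region is imbalanced. Because
#' the two alleles deviate symmetrically (SNPs with the B allele on the
#' gained/retained homologue rise above 0.5, the others mirror below),
#' frequencies are folded about 0.5 (`max(af, 1 - af)`) before taking the
#' median by default; otherwise the plain median of a two-sided scatter
#' sits at 0.5 regardless of imbalance. Even counts take the mean of the
#' two middle values.
#'
#' @param afs Numeric vector of het-SNP allele frequencies in `[0, 1]`.
#' @param fold Fold about 0.5 first (default `TRUE`).
#' @return The median allele frequency.
#' @export
region_median_het_af <- function(afs, fold = TRUE) {
  if (length(afs) == 0) stop("no heterozygous SNPs in region")
  if (any(afs < 0 | afs > 1)) stop("allele frequencies must lie in [0, 1]")
  if (fold) afs <- pmax(afs, 1 - afs)
  stats::median(afs)
}

#' Clonality of a CNV region
#'
#' The median het-SNP allele frequency is corrected for tumour content by
#' scaling its deviation from the balanced 50%:
#' `f~' = 0.5 + (median_af - 0.5) / tc`, clipped to `[0, 1]`. Clonality is
#' twice the absolute deviation of the corrected frequency from 50%:
#' `c = min(2 |f~' - 0.5|, 1)`. A balanced region gives `c = 0` at any
#' purity.
#'
#' @param median_af Median het-SNP allele frequency in `[0, 1]`.
#' @param tc Tumour content in `(0, 1]`.
#' @return Clonality in `[0, 1]`.
#' @export
cnv_clonality <- function(median_af, tc) {
  if (length(tc) != 1 || tc <= 0 || tc > 1) stop("tc must lie in (0, 1]")
  if (any(median_af < 0 | median_af > 1)) {
    stop("median_af must lie in [0, 1]")
  }
  f_corr <- pmin(pmax(0.5 + (median_af - 0.5) / tc, 0), 1)
  pmin(2 * abs(f_corr - 0.5), 1)
}

#' Per-alteration clonality estimates for a tumour sample
#'
#' Computes the raw frequency, corrected frequency and clonality of every
#' diploid-region SNV/InDel and of every high-confidence CNV region.
#'
#' @param sample A [tumour_sample()].
#' @param ... Passed to [is_high_confidence_region()].
#' @return data.frame with `id`, `type` (`SNV`, `InDel`, `amplification`,
#'   `deletion`), `f`, `f_corrected`, `clonality`, `c_allele1`,
#'   `c_allele2`.
#' @export
clonality_estimates <- function(sample, ...) {
  tc <- sample$tumour_content
  muts <- select_diploid_mutations(sample, ...)
  out <- list()
  if (nrow(muts) > 0) {
    f <- allele_frequency(muts)
    fc <- correct_allele_frequency(f, tc)
    cl <- mutation_clonality(fc)
    out[[1]] <- data.frame(
      id = variant_key(muts),
      type = ifelse(muts$kind == "SNV", "SNV", "InDel"),
      f = f, f_corrected = fc, clonality = cl$c,
      c_allele1 = cl$c_allele1, c_allele2 = cl$c_allele2,
      stringsAsFactors = FALSE)
  }
  segs <- sample$segments
  if (nrow(segs) > 0) {
    hc <- segs[is_high_confidence_region(segs, ...), , drop = FALSE]
    if (nrow(hc) > 0) {
      med <- vapply(hc$het_snp_afs, region_median_het_af, numeric(1))
      fc <- pmin(pmax(0.5 + (med - 0.5) / tc, 0), 1)
      out[[length(out) + 1]] <- data.frame(
        id = paste0(hc$chrom, ":", hc$start, "-", hc$end),
        type = ifelse(hc$copy_number > 2, "amplification", "deletion"),
        f = med, f_corrected = fc,
        clonality = cnv_clonality(med, tc),
        c_allele1 = NA_real_, c_allele2 = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(id = character(0), type = character(0),
                      f = numeric(0), f_corrected = numeric(0),
                      clonality = numeric(0), c_allele1 = numeric(0),
                      c_allele2 = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Clonality density and expected alteration counts
#'
#' One-dimensional Gaussian kernel density of the clonality values,
#' evaluated on an even grid over `[0, 1]` and renormalised to unit
#' trapezoid integral on that interval (the kernel leaks mass outside the
#' unit interval near the boundaries). The expected number of alterations
#' in each grid interval is the contained probability mass times the
#' total number of alterations, rescaled to sum exactly to `n`.
#'
#' @param cs Numeric vector of clonality values (at least 2).
#' @param grid_size Number of evaluation points (default 512).
#' @param bw Kernel bandwidth; default is the Silverman normal-reference
#'   rule (`stats::bw.nrd0`), with a floor of 0.01 for degenerate inputs.
#' @return List of class `"clonality_density"` with `grid`, `density`,
#'   `n`, `expected_counts` (length `grid_size - 1`, one per interval).
#' @export
clonality_density <- function(cs, grid_size = 512, bw = NULL) {
  if (length(cs) < 2) stop("need at least 2 clonality values")
  if (any(cs < 0 | cs > 1)) stop("clonality values must lie in [0, 1]")
  if (is.null(bw)) {
    bw <- if (stats::sd(cs) == 0) 0.01 else max(stats::bw.nrd0(cs), 0.01)
  }
  d <- stats::density(cs, bw = bw, from = 0, to = 1, n = grid_size)
  total <- .trapz(d$x, d$y)
  rho <- d$y / total
  dx <- diff(d$x)
  mass <- dx * (utils::head(rho, -1) + utils::tail(rho, -1)) / 2
  n <- length(cs)
  expected <- mass / sum(mass) * n
  structure(list(grid = d$x, density = rho, n = n, bw = bw,
                 expected_counts = expected),
            class = "clonality_density")
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Expected number of alterations in a clonality interval
#'
#' @param density A [clonality_density()].
#' @param lower,upper Interval bounds within `[0, 1]`.
#' @return Expected count (probability mass of the interval times `n`).
#' @export
expected_alterations <- function(density, lower, upper) {
  mids <- (utils::head(density$grid, -1) + utils::tail(density$grid, -1)) / 2
  sum(density$expected_counts[mids >= lower & mids < upper])
}

#' Classify the clone composition of a tumour
#'
#' Alterations are binned by clonality: low (`c < 0.35`), mid
#' (`0.35 <= c <= 0.80`) and high (`c > 0.80`); both boundaries belong to
#' the mid bin. The largest bin names the composition: high = monoclonal
#' (one prevalent clone), mid = biclonal, low = polyclonal. Ties go to
#' the less clonal label (polyclonal over biclonal over monoclonal),
#' conservative against overcalling monoclonality.
#'
#' @param clonalities Numeric vector of clonality values (or the
#'   `clonality` column of [clonality_estimates()]).
#' @param low_cut,high_cut Bin boundaries (defaults 0.35 and 0.80).
#' @return List of class `"clone_composition"` with `counts` (named:
#'   low/mid/high) and `label`.
#' @export
classify_clone_composition <- function(clonalities, low_cut = 0.35,
                                       high_cut = 0.80) {
  if (length(clonalities) == 0) stop("no clonality estimates supplied")
  if (any(clonalities < 0 | clonalities > 1)) {
    stop("clonality values must lie in [0, 1]")
  }
  counts <- c(low = sum(clonalities < low_cut),
              mid = sum(clonalities >= low_cut & clonalities <= high_cut),
              high = sum(clonalities > high_cut))
  # order encodes the tie-break: least clonal label wins ties
  labels <- c(low = "polyclonal", mid = "biclonal", high = "monoclonal")
  ordered <- c("low", "mid", "high")
  best <- ordered[which.max(counts[ordered])]
  structure(list(counts = counts, label = unname(labels[best])),
            class = "clone_composition")
}
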