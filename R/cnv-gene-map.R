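# Copy-number segment to gene assignment. High-confidence aberrant
# regions combine the array call (copy number != 2, reliability > 75%)
# with a non-normality screen on heterozygous-SNP allele frequencies:
# in a diploid region het SNPs scatter normally around 50%, while
# allelic imbalance skews the distribution. Genes are called amplified
# or deleted when >= 80% of their length lies in aberrant regions of one
# direction; putative drivers follow the cancer-gene role rules.

#' High-confidence aberrant region rule
#'
#' A segment is a high-confidence aberration when its copy number differs
#' from 2, its aberration reliability score exceeds `min_reliability`,
#' and a normality test on the heterozygous-SNP allele frequencies inside
#' it rejects at level `alpha` (the het-SNP scatter of a diploid region
#' is normal around 0.5; imbalance breaks that). Segments with fewer than
#' `min_snps` het SNPs fail the screen. Zero-variance AF vectors (all
#' identical) count as rejecting normality.
#'
#' @param segments A [cnv_segments()] table.
#' @param alpha Significance level of the normality screen (default 0.05).
#' @param min_reliability Reliability must be strictly greater (default 75).
#' @param min_snps Minimum het SNPs for the screen (default 3).
#' @param normality_test Function taking a numeric vector and returning a
#'   p-value; defaults to Shapiro-Wilk.
#' @return Logical vector, one per segment.
#' @export
is_high_confidence_region <- function(segments, alpha = 0.05,
                                      min_reliability = 75, min_snps = 3,
                                      normality_test = function(x)
                                        stats::shapiro.test(x)$p.value) {
  vapply(seq_len(nrow(segments)), function(i) {
    if (segments$copy_number[i] == 2) return(FALSE)
    if (!(segments$reliability[i] > min_reliability)) return(FALSE)
    afs <- segments$het_snp_afs[[i]]
    if (length(afs) < min_snps) return(FALSE)
    if (stats::sd(afs) == 0) return(TRUE)
    normality_test(afs) < alpha
  }, logical(1))
}

.direction_coverage <- function(gene, regions) {
  # fraction of the gene body covered by the union of `regions`
  same <- regions[regions$chrom == gene$chrom, , drop = FALSE]
  if (nrow(same) == 0) return(0)
  g <- IRanges::IRanges(start = gene$start + 1L, end = gene$end)
  r <- IRanges::reduce(IRanges::IRanges(start = same$start + 1L,
                                        end = same$end))
  hit <- IRanges::intersect(r, g)
  sum(IRanges::width(hit)) / (gene$end - gene$start)
}

#' Copy-number status of a gene
#'
#' A gene is `amplified` when at least `min_overlap` of its length is
#' covered by (the union of) gained regions (copy number > 2), `deleted`
#' when at least `min_overlap` is covered by lost regions (< 2), and
#' `neutral` otherwise. Gains and losses accumulate separately: mixed
#' coverage never sums. Disjoint aberrant regions of one direction may
#' jointly reach the threshold.
#'
#' @param gene One-row [gene_models()] entry (or list with `chrom`,
#'   `start`, `end`, `symbol`).
#' @param regions A [cnv_segments()] table of high-confidence aberrant
#'   regions.
#' @param min_overlap Required covered fraction of the gene (default 0.8).
#' @return List with `symbol`, `status`, `overlap_fraction` (the covered
#'   fraction in the called direction, or the larger of the two when
#'   neutral).
#' @export
gene_cnv_status <- function(gene, regions, min_overlap = 0.8) {
  if (gene$end - gene$start <= 0) stop("gene length must be positive")
  amp <- .direction_coverage(gene, regions[regions$copy_number > 2, ,
                                           drop = FALSE])
  del <- .direction_coverage(gene, regions[regions$copy_number < 2, ,
                                           drop = FALSE])
  if (amp >= min_overlap) {
    list(symbol = gene$symbol, status = "amplified", overlap_fraction = amp)
  } else if (del >= min_overlap) {
    list(symbol = gene$symbol, status = "deleted", overlap_fraction = del)
  } else {
    list(symbol = gene$symbol, status = "neutral",
         overlap_fraction = max(amp, del))
  }
}

#' Copy-number status for a table of genes
#'
#' @param genes A [gene_models()] table.
#' @param regions High-confidence aberrant regions ([cnv_segments()]).
#' @param min_overlap See [gene_cnv_status()].
#' @return data.frame with `symbol`, `status`, `overlap_fraction`.
#' @export
genes_cnv_status <- function(genes, regions, min_overlap = 0.8) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    as.data.frame(gene_cnv_status(genes[i, ], regions, min_overlap))
  })
  do.call(rbind, rows)
}

#' Classify putative driver alterations in a tumour sample
#'
#' A cancer gene is a putative driver when it (1) harbours at least one
#' nonsilent somatic mutation, or (2) is an oncogene amplified inside a
#' recurrently modified region, or (3) is a tumour suppressor deleted
#' inside a recurrently modified region. "Inside" means the gene midpoint
#' falls within a recurrent interval. Copy-number status is computed on
#' the sample's high-confidence aberrant regions.
#'
#' @param sample A [tumour_sample()].
#' @param cancer_genes A [gene_models()] table with `role` annotated.
#' @param recurrent_regions data.frame of recurrent intervals (`chrom`,
#'   `start`, `end`, 0-based half-open); may have zero rows.
#' @param ... Passed to [is_high_confidence_region()].
#' @return data.frame with `gene` and `evidence` (comma-joined subset of
#'   `nonsilent_mutation`, `oncogene_amplified`, `tsg_deleted`); genes
#'   without evidence are omitted.
#' @export
classify_putative_drivers <- function(sample, cancer_genes,
                                      recurrent_regions =
                                        data.frame(chrom = character(0),
                                                   start = integer(0),
                                                   end = integer(0)),
                                      ...) {
  hc <- sample$segments[is_high_confidence_region(sample$segments, ...), ,
                        drop = FALSE]
  nonsilent_genes <- unique(
    sample$variants$gene[sample$variants$effect %in% .nonsilent_effects])
  midpoint_recurrent <- function(gene) {
    if (nrow(recurrent_regions) == 0) return(FALSE)
    mid <- (gene$start + gene$end) / 2
    any(recurrent_regions$chrom == gene$chrom &
          recurrent_regions$start <= mid & mid < recurrent_regions$end)
  }
  rows <- lapply(seq_len(nrow(cancer_genes)), function(i) {
    gene <- cancer_genes[i, ]
    evidence <- character(0)
    if (gene$symbol %in% nonsilent_genes) {
      evidence <- c(evidence, "nonsilent_mutation")
    }
    status <- gene_cnv_status(gene, hc)$status
    if (midpoint_recurrent(gene)) {
      if (gene$role == "oncogene" && status == "amplified") {
        evidence <- c(evidence, "oncogene_amplified")
      }
      if (gene$role == "tumour_suppressor" && status == "deleted") {
        evidence <- c(evidence, "tsg_deleted")
      }
    }
    if (length(evidence) == 0) return(NULL)
    data.frame(gene = gene$symbol,
               evidence = paste(evidence, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), evidence = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
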