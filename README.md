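# syclone

Cohort-level genomic analysis of synchronous colorectal cancers (and,
generally, of any matched tumour cohorts): reconstruction of tumour
**clone composition** from purity-corrected allele frequencies,
**rare damaging germline variant** filtering, **CNV-to-gene** mapping
with putative-driver rules, the **MEGA** mutation-enrichment gene-set
analysis with a down-sampling bootstrap, and **expression-class**
gene-set enrichment on TPM matrices. Synthetic-data generators with
known ground truth make every stage testable without access to
controlled patient data.

## The models in brief

**Clonality.** The clonality *c* of an alteration is the fraction of
cancer cells carrying it. For a heterozygous mutation in a diploid
region observed at raw allele frequency *f* in a specimen of tumour
content (purity) *tc*:

    f' = min(f / tc, 1)          (purity correction)
    c  = 2 f'          for f' ≤ 0.5
    c  = 1             for f' > 0.5 (almost clonal; allele
                        clonalities c1 = 1, c2 = 2f' − 1)

CNV-region clonality uses the median heterozygous-SNP allele frequency
(folded about 0.5): `c = min(2 |0.5 + (median − 0.5)/tc − 0.5|, 1)`.
Alterations are binned by clonality (> 0.80 / 0.35–0.80 / < 0.35) and
the largest bin labels the tumour monoclonal, biclonal or polyclonal.

**MEGA.** For a gene set *X*, the per-sample burden is the number of
mutations in genes of *X*. Burden distributions of two cohorts are
compared with the one-tailed Wilcoxon rank-sum test (exact permutation
null for combined n ≤ 20, ties included), Benjamini–Hochberg corrected
across sets. Unbalanced cohorts get a bootstrap: the larger cohort is
down-sampled with replacement to the smaller one's size 10,000 times
and the proportion of significant comparisons (p < 0.05) reported.

**Expression classes.** Per sample, genes are *not expressed*
(TPM < 0.1, takes precedence), *high* (> 75th percentile), *low*
(< 25th) or *medium*. Class fractions per gene set are compared between
cohorts with Fisher's exact test on pooled (gene, sample) pairs, with
the same style of down-sampling bootstrap.

## Worked example

```r
library(syclone)

# A biclonal tumour: truncal clone plus a half-prevalence subclone
s <- simulate_tumour_class("biclonal", tc = 0.7, depth = 200,
                           n_mutations = 150, seed = 7)
est <- clonality_estimates(s)
classify_clone_composition(est$clonality)
#> $counts
#>  low  mid high
#>    5   95   50
#> $label
#> [1] "biclonal"
```

95 of 150 somatic mutations have clonality in the mid bin (0.35–0.80):
the mutations private to the prevalence-0.5 subclone, plus clipping
spillover from the truncal clone — the signature of two prevalent
clones, so the tumour is labelled biclonal.

```r
# MEGA on cohorts (33 vs 406 samples) with a planted burden enrichment
genes <- sprintf("G%03d", 1:100)
sets <- list(TARGET = genes[1:20], CONTROL = genes[21:40])
sim <- simulate_mega_cohorts(33, 406, genes, sets,
                             background_rate = 0.3 / 20,
                             enriched_sets = "TARGET",
                             multiplier = 1 / 0.3, seed = 11)
mega_scan(sets, sim$cohort_a, sim$cohort_b)
#>       set n_a n_b median_a median_b        p        q
#> 1  TARGET  33 406        1        0 1.37e-12 2.74e-12
#> 2 CONTROL  33 406        0        0 6.18e-02 6.18e-02

mega_bootstrap(sets$TARGET, sim$cohort_a, sim$cohort_b,
               n_iter = 200, seed = 12)
#> [1] 1
```

The planted set (mean burden 1.0 per sample in cohort A vs 0.3 in
cohort B — the regime observed in the motivating cohorts) is strongly
significant after FDR correction; the control set is not. The bootstrap
proportion of 1 means every down-sampled 33-vs-33 comparison stayed
significant, so the enrichment is not an artifact of the unequal
cohort sizes.

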