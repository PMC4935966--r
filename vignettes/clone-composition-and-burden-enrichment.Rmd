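---
title: "Clone composition, mutation burden enrichment and expression classes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone composition, mutation burden enrichment and expression classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syclone)
```

# Scope

`syclone` implements the computational stack used to characterise
synchronous colorectal cancers at the cohort level: somatic and germline
variant filters, reconstruction of tumour clone composition from
purity-corrected allele frequencies, copy-number-to-gene mapping with
putative-driver rules, a mutation-enrichment gene-set analysis (MEGA)
with a down-sampling bootstrap for unbalanced cohorts, and an
expression-class enrichment analysis on TPM matrices. Everything runs on
plain tab-separated tables (plus GMT gene sets and BED gene models), and
synthetic-data generators provide inputs with known ground truth so that
every stage can be validated end to end.

# Variant filtering model

Tumour calls are retained when supported by at least 10 mutated reads,
an allele frequency of at least 5%, and at least 1% of supporting reads
on each DNA strand (a strand-bias guard). Matched-normal calls need only
two mutated reads plus the strand rule: the normal sample is used as a
*blacklist* for somatic subtraction, so its filter errs towards
sensitivity. When a sample is sequenced twice from independent
libraries, tumour calls must appear in both rounds (artifacts rarely
replicate), while normal rounds are merged by union; merged records keep
the first round's read counts, an arbitrary but documented choice since
concordant calls have interchangeable support.

The germline chain for rare damaging SNPs keeps variants with at least
10 mutated reads, the strand rule, and an allele frequency compatible
with a genotype: 40–60% (heterozygous, inclusive) or strictly above 90%
(homozygous). A variant is *damaging* if it is stopgain/stoploss, or
nonsynonymous and called damaging by at least four of the five
predictors (SIFT, PolyPhen2, MutationTaster, MutationAssessor, LRT). A
missing predictor call counts as a non-damaging vote by default, so
"four of five" is applied literally with a fixed denominator; an
abstention mode that shrinks the denominator is available
(`missing_as_abstention = TRUE`) for sensitivity analyses. A variant is
*rare* when every available population panel reports MAF < 1%; absence
from all panels counts as rare. Finally, keys absent from the panels but
carried by more than 50% of samples (pooled across cohorts by default;
strictly greater) are removed as recurrent alignment artifacts — a real
variant that common would be in the panels. A per-cohort mode (removed
only if common in *every* cohort) is available; the pooled reading is
the stronger filter and matches the rule's purpose.

Variant identity is `(chrom, pos, ref, alt)` after a reference-free
normalisation (shared suffix then shared prefix trimmed, position
advanced). Full left-alignment would require the reference genome;
within one pipeline the same representation convention applies to both
lists being compared, so the reference-free form is sufficient.

# Clonality model

The clonality *c* of an alteration is the fraction of cancer cells that
carry it. For a heterozygous mutation in a diploid region, a specimen
of tumour content (purity) `tc` dilutes the mutant allele with
wild-type alleles from normal cells, so the corrected frequency is
`f' = min(f / tc, 1)` and the clonality `c = 2 f'` (two alleles per
cell). For `0.5 < f' <= 1` (*almost clonal*) the excess is attributed
to a second mutated allele in part of the cells: allele clonalities
`c1 = 1` and `c2 = 2 f' − 1`, with cell-level clonality
`c = min(2 f', 1) = 1` — every cancer cell carries at least one mutated
allele. This treatment is continuous at `f' = 0.5`, monotone in `f`,
and coincides with the standard cancer-cell-fraction convention.
Mutations inside amplified or deleted regions are excluded upstream
(`select_diploid_mutations()`) because copy number distorts `f`.

For CNV regions, heterozygous SNPs (40–60% allele frequency in the
matched normal) deviate from 50% under allelic imbalance. The region's
allele frequency is the median het-SNP frequency; frequencies are
folded about 0.5 before the median (`max(af, 1 − af)`) because the two
alleles deviate symmetrically and the plain median of a two-sided
scatter sits at 0.5 regardless of imbalance (`fold = FALSE` restores
the plain median). The purity correction scales the deviation,
`f~' = 0.5 + (median − 0.5)/tc`, and `c = min(2 |f~' − 0.5|, 1)`. This
estimator is exact for single-copy losses, where the affected-cell
allele ratio is 0 or 1: the expected folded deviation is `tc·c/2`, so
doubling after the purity correction recovers `c`. For single-copy
gains the affected-cell ratio is 2/3, whose deviation from 0.5 is only
1/6, so the same estimator *underestimates* gain clonality by a factor
of three — a known property of the deviation-doubling rule, which is why
the recovery checks in the test suite use deletions.

## High-confidence aberrant regions

A segment qualifies when its copy number differs from 2, its
aberration reliability score exceeds 75, and the het-SNP allele
frequencies inside it reject normality. No specific normality test is
prescribed by the approach; Shapiro–Wilk at `alpha = 0.05` with at
least 3 SNPs is the default and the test function is pluggable. A
zero-variance AF vector (all SNPs identical) is treated as rejecting
normality: it is degenerate evidence of imbalance, not of a diploid
scatter.

## Density and classification

The clonality density is a one-dimensional Gaussian kernel estimate
with the Silverman normal-reference bandwidth (`stats::bw.nrd0`,
configurable), evaluated on an even grid over [0, 1] and renormalised
to unit trapezoid integral there, since the kernel leaks mass outside
the unit interval near the boundaries. Expected alteration counts per
grid interval are the contained probability mass times the number of
alterations, rescaled to sum exactly to *n*.

Tumours are classified by binning alteration clonalities at 0.35 and
0.80: low (< 0.35), mid (0.35–0.80, both boundaries included) and high
(> 0.80). The largest bin names the composition — monoclonal, biclonal
or polyclonal respectively — and ties go to the *less* clonal label,
conservative against overcalling monoclonality. Per-type densities
(SNV, InDel, amplification, deletion) can be drawn independently, but
the classification pools all estimates, since one label describes one
tumour.

# MEGA

For a gene set *X* and cohorts *A*, *B*, the per-sample burden is the
number of mutations in genes of *X*; the burden distributions `D_A` and
`D_B` are compared with the one-tailed Wilcoxon rank-sum test (is *A*
enriched?). Across many sets, p-values are Benjamini–Hochberg corrected
over *all* input sets. For small samples (combined n ≤ 20) the exact
permutation null is enumerated on midranks — exact even with tied
burdens, which are the norm for count data; larger samples use the
normal approximation with tie and continuity corrections.

When cohort sizes differ substantially, the down-sampling bootstrap
resamples the larger cohort **with replacement** to the smaller
cohort's size (the smaller cohort stays fixed), repeats the comparison
`n_iter` times (10,000 by default) and reports the proportion of
significant iterations (p < 0.05). With equal sizes the proportion
degenerates to the indicator of the single comparison. A single integer
seed makes the proportion bit-reproducible.

# Expression classes

TPM values (or scaled estimates × 10⁶) are classified per sample from
the sample's own distribution: *not expressed* if TPM < 0.1 (this rule
takes precedence), *high* if strictly above the 75th percentile, *low*
if strictly below the 25th, *medium* otherwise. Percentiles use the
linear-interpolation quantile definition (type 7) over the full gene
universe, including genes later labelled not expressed — the floor rule
is a detection statement, the percentiles a rank statement, and
computing ranks on the full universe keeps the class sizes stable
across samples. Labels therefore depend only on ranks above the floor.

Per gene set and class, cohorts are compared by pooling (gene, sample)
pairs into a 2×2 table (cohort × in-class/other) and applying Fisher's
exact test, BH-corrected across sets; a per-sample-mean mode (rank-sum
on per-sample in-class fractions) is exposed for sensitivity analysis
since "cumulative proportion" admits both readings. The expression
bootstrap mirrors MEGA's but samples the larger cohort *without*
replacement within an iteration, matching a "randomly selected
subsamples" design.

# Synthetic data

The generators invert the models above so recovery can be scored:

* `simulate_tumour()`: per mutation, total reads ~ Poisson(depth)
  (a zero draw is replaced by 1 so the frequency exists), mutated reads
  ~ Binomial(total, `c·tc/2`), strand split Binomial(alt, 0.5). The
  generating clone of each mutation is recorded.
* `simulate_tumour_class()` encodes three canonical architectures:
  monoclonal (one clone at prevalence 1), biclonal (truncal clone at 1
  with 1/3 of mutations plus a subclone at 0.5 carrying 2/3 — the
  expanding-subclone picture in which mid-clonality alterations
  dominate) and polyclonal (three minor clones at 0.25/0.20/0.15,
  equal shares).
* `simulate_cnv_segment()`: het-SNP expected AFs mix normal cells,
  unaffected and affected cancer cells by their cell fractions, with
  the affected-cell allele ratio set by the copy number under a
  single-allele change; each SNP's B allele lands on the affected
  homologue with probability 0.5, so AFs scatter on both sides of 0.5.
* `simulate_mega_cohorts()`: per-gene per-sample Poisson counts, rate
  multiplied in enriched sets for cohort A only. The observed regime of
  the motivating cohorts — ~1.0 rare damaging SNPs per patient in the
  enriched set versus ~0.3 — corresponds to
  `background_rate = 0.3/set_size`, `multiplier = 1/0.3`.
* `simulate_expression_cohorts()`: baseline log-normal TPMs
  (meanlog 3, sdlog 2 — a realistic bulk RNA-seq spread with a few
  percent of genes under the 0.1 TPM floor); a chosen fraction of a
  suppressed set's genes is forced below 0.1 in every cohort-A sample.

One master seed drives a named substream per generator, so adding one
generator never perturbs another's draws. Not modelled on purpose:
realistic genome coordinates, trinucleotide signatures, FFPE artifacts,
overdispersed coverage (the Poisson–binomial model is the standard
exome noise model). Consequently, passing recovery tests demonstrate
correctness of the estimators under their own assumptions, not
robustness to the full error structure of archival tissue sequencing.

# Validation problem sizes

The acceptance checks run at sizes chosen to keep the whole suite in a
few minutes while leaving comfortable statistical margins: 300
simulated tumours (100 per architecture; purity Uniform(0.4, 0.9),
depth 200, 150 mutations) for ≥90% classification accuracy; depth 500
and 300 mutations for the ≤0.03 single-clone error; 2,000 replicates
for null calibration of the one-tailed comparison; 1,000 bootstrap
iterations at cohort sizes 33 vs 406 for power; 200 replicates × 50
gene sets for the planted-suppression ranking; full enumeration oracles
for every rank-sum design up to 7 + 7, 200 Fisher tables of total ≤ 40
and 1,000 random gene/region layouts.

# Worked example

```{r example}
# a biclonal tumour: truncal clone plus a half-prevalence subclone
s <- simulate_tumour_class("biclonal", tc = 0.7, depth = 200,
                           n_mutations = 150, seed = 7)
est <- clonality_estimates(s)
classify_clone_composition(est$clonality)

# MEGA on cohorts with a planted burden enrichment
genes <- sprintf("G%03d", 1:100)
sets <- list(TARGET = genes[1:20], CONTROL = genes[21:40])
sim <- simulate_mega_cohorts(33, 406, genes, sets,
                             background_rate = 0.3 / 20,
                             enriched_sets = "TARGET",
                             multiplier = 1 / 0.3, seed = 11)
mega_scan(sets, sim$cohort_a, sim$cohort_b)
mega_bootstrap(sets$TARGET, sim$cohort_a, sim$cohort_b,
               n_iter = 200, seed = 12)
```

# Known limitations

* The CNV clonality estimator is calibrated to losses; gains are
  systematically underestimated (see above) and should be interpreted
  qualitatively.
* The almost-clonal allele split reports `c = 1` for any `f' > 0.5`;
  genuinely homozygous subclonal mutations are indistinguishable from
  clonal heterozygous ones without local copy-number genotypes.
* The artifact filter's pooled-versus-per-cohort reading changes which
  keys are removed when cohort sizes are very unequal; both modes are
  exposed.
* Percentile classes are within-sample: cross-sample comparisons of
  class fractions are meaningful, absolute expression levels are not
  preserved.
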