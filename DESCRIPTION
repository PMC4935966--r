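Package: syclone
Title: Clone Composition, Mutation Burden Enrichment and Expression-Class
    Analysis for Synchronous Colorectal Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing tumour clone composition from
    purity-corrected variant allele frequencies, for filtering somatic and
    rare damaging germline variants, for mapping copy-number segments to
    genes and putative driver alterations, for the mutation-enrichment
    gene-set analysis (MEGA) comparing per-sample mutation burdens between
    cohorts with a down-sampling bootstrap, and for expression-class
    gene-set enrichment on TPM matrices. Includes synthetic-data generators
    that emulate multi-clone tumours, allelic imbalance in copy-number
    regions, cohort-level mutation burdens and suppressed-pathway
    expression, so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
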