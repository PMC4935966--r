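test_that("simulated tumours honour the read model and are deterministic", {
  s1 <- simulate_tumour(list(clone_spec(1, 500)), tc = 0.5, depth = 400,
                        seed = 101)
  s2 <- simulate_tumour(list(clone_spec(1, 500)), tc = 0.5, depth = 400,
                        seed = 101)
  expect_identical(as.data.frame(s1$variants), as.data.frame(s2$variants))
  # expected raw VAF of a clonal mutation is c * tc / 2 = 0.25
  expect_lt(abs(mean(allele_frequency(s1$variants)) - 0.25), 0.01)
  # truth sidecar aligns with the variants
  truth <- attr(s1, "truth")
  expect_equal(truth$id, variant_key(s1$variants))

  zero <- simulate_tumour(list(clone_spec(1e-9, 50)), tc = 0.5,
                          depth = 100, seed = 1)
  expect_true(all(zero$variants$alt_reads == 0))
  expect_error(simulate_tumour(list(clone_spec(1, 10)), tc = 1.5,
                               depth = 100), "tc")
})

test_that("simulated tumours round-trip through the variant IO", {
  s <- simulate_tumour(list(clone_spec(0.6, 40)), tc = 0.7, depth = 150,
                       seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(s$variants, path)
  back <- read_variant_table(path)
  expect_equal(as.data.frame(back), as.data.frame(s$variants))
})

test_that("simulated CNV segments show the expected allelic imbalance", {
  # clonal single-copy gain in a pure tumour: AFs near 2/3 or 1/3
  seg <- simulate_cnv_segment(3L, clonality = 1, tc = 1, n_snps = 200,
                              depth = 5000, seed = 11)
  afs <- seg$het_snp_afs[[1]]
  folded <- pmax(afs, 1 - afs)
  expect_lt(abs(median(folded) - 2/3), 0.02)

  # zero clonality: everything centres on 0.5
  seg0 <- simulate_cnv_segment(3L, clonality = 0, tc = 0.8, n_snps = 200,
                               depth = 2000, seed = 12)
  expect_lt(abs(mean(seg0$het_snp_afs[[1]]) - 0.5), 0.02)

  expect_error(simulate_cnv_segment(2L, clonality = 0.5, tc = 0.8,
                                    n_snps = 10, depth = 100), "CN=2")
  # determinism
  a <- simulate_cnv_segment(1L, 0.5, 0.7, 20, 500, seed = 13)
  b <- simulate_cnv_segment(1L, 0.5, 0.7, 20, 500, seed = 13)
  expect_identical(a$het_snp_afs, b$het_snp_afs)
})

test_that("simulated mega cohorts are exchangeable at multiplier one and
           enriched otherwise", {
  genes <- sprintf("G%03d", 1:200)
  sets <- list(TARGET = genes[1:30], OTHER = genes[31:60])
  null_sim <- simulate_mega_cohorts(15, 15, genes, sets,
                                    background_rate = 0.01, seed = 21)
  expect_identical(dim(null_sim$cohort_a), c(200L, 15L))

  enr <- simulate_mega_cohorts(30, 30, genes, sets,
                               background_rate = 0.01,
                               enriched_sets = "TARGET",
                               multiplier = 50, seed = 22)
  p_target <- mega_test(sets$TARGET, enr$cohort_a, enr$cohort_b)
  p_other <- mega_test(sets$OTHER, enr$cohort_a, enr$cohort_b)
  expect_lt(p_target, 0.001)
  expect_gt(p_other, 0.01)
  expect_equal(enr$truth$enriched_sets, "TARGET")

  # same seed, same draws
  r1 <- simulate_mega_cohorts(5, 5, genes, sets, seed = 23)
  r2 <- simulate_mega_cohorts(5, 5, genes, sets, seed = 23)
  expect_identical(r1$cohort_a, r2$cohort_a)
})

test_that("burden calibration to the observed cohort regime holds", {
  # mean rare-damaging burden of ~1.0 per patient (cohort A) vs ~0.3
  # (cohort B) inside the target set
  genes <- sprintf("G%03d", 1:100)
  sets <- list(TARGET = genes[1:20])
  sim <- simulate_mega_cohorts(200, 200, genes, sets,
                               background_rate = 0.3 / 20,
                               enriched_sets = "TARGET",
                               multiplier = 1.0 / 0.3, seed = 31)
  ba <- cohort_burdens(sets$TARGET, sim$cohort_a)
  bb <- cohort_burdens(sets$TARGET, sim$cohort_b)
  expect_lt(abs(mean(ba) - 1.0), 0.15)
  expect_lt(abs(mean(bb) - 0.3), 0.1)
})

test_that("suppressed expression cohorts carry the planted signal and
           write/read cleanly", {
  genes <- sprintf("G%03d", 1:100)
  sets <- list(SUP = genes[1:50])
  sim <- simulate_expression_cohorts(6, 6, genes, suppressed_sets = sets,
                                     suppression_fraction = 0.10,
                                     seed = 41)
  expect_equal(length(sim$truth$suppressed_genes), 5)  # 10% of 50
  a <- unclass(sim$cohort_a)
  expect_true(all(a[sim$truth$suppressed_genes, ] < 0.1))

  # suppression_fraction 0: exchangeable, no truth entries
  null_sim <- simulate_expression_cohorts(4, 4, genes,
                                          suppressed_sets = sets,
                                          suppression_fraction = 0,
                                          seed = 42)
  expect_length(null_sim$truth$suppressed_genes, 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$cohort_a, path)
  back <- read_expression_matrix(path)
  expect_equal(dim(back), dim(sim$cohort_a))

  r1 <- simulate_expression_cohorts(3, 3, genes, seed = 43)
  r2 <- simulate_expression_cohorts(3, 3, genes, seed = 43)
  expect_identical(unclass(r1$cohort_a), unclass(r2$cohort_a))
})

test_that("class presets produce the intended architectures", {
  s <- simulate_tumour_class("biclonal", tc = 0.7, depth = 300,
                             n_mutations = 150, seed = 51)
  truth <- attr(s, "truth")
  expect_setequal(unique(truth$clone_prevalence), c(1.0, 0.5))
  # the subclone carries the majority of private mutations
  expect_gt(sum(truth$clone_prevalence == 0.5),
            sum(truth$clone_prevalence == 1.0))
  expect_equal(nrow(s$variants), 150)
})
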