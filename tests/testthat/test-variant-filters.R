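test_that("tumour filters enforce read support, frequency and strand rules", {
  # all three boundaries met exactly
  v <- make_variants(1, alt_reads = 10L, total_reads = 200L)
  expect_true(pass_tumour_filters(v)$passed)

  v <- make_variants(1, alt_reads = 9L, total_reads = 20L)
  d <- pass_tumour_filters(v)
  expect_false(d$passed)
  expect_match(d$failed_rules, "min_alt_reads")

  v <- make_variants(1, alt_reads = 50L, total_reads = 100L,
                     frac_plus = 0.995, frac_minus = 0.005)
  d <- pass_tumour_filters(v)
  expect_false(d$passed)
  expect_match(d$failed_rules, "strand_balance")

  v <- make_variants(1, alt_reads = 10L, total_reads = 300L)
  expect_match(pass_tumour_filters(v)$failed_rules, "min_af")

  v <- make_variants(1, alt_reads = 0L, total_reads = 0L)
  expect_error(pass_tumour_filters(v), "undefined")
})

test_that("normal filters need only two supporting reads", {
  v <- make_variants(1, alt_reads = 2L, total_reads = 50L,
                     frac_plus = 0.9, frac_minus = 0.1)
  expect_true(pass_normal_filters(v)$passed)
  expect_false(pass_normal_filters(
    make_variants(1, alt_reads = 1L))$passed)
  expect_false(pass_normal_filters(
    make_variants(1, alt_reads = 5L, frac_plus = 1.0,
                  frac_minus = 0.0))$passed)
})

test_that("sequencing rounds intersect for tumours and unite for normals", {
  r1 <- make_variants(2, pos = c(100L, 200L))
  r2 <- make_variants(2, pos = c(200L, 300L))
  tum <- merge_sequencing_rounds(r1, r2, mode = "tumour")
  expect_equal(tum$pos, 200L)
  # merged counts come from round1
  r2b <- make_variants(2, pos = c(200L, 300L), alt_reads = 55L)
  tum2 <- merge_sequencing_rounds(r1, r2b, mode = "tumour")
  expect_equal(tum2$alt_reads, r1$alt_reads[2])

  nor <- merge_sequencing_rounds(r1, r2, mode = "normal")
  expect_setequal(nor$pos, c(100L, 200L, 300L))

  same <- merge_sequencing_rounds(r1, r1, mode = "tumour")
  expect_equal(as.data.frame(same), as.data.frame(r1))
})

test_that("germline subtraction partitions the tumour set", {
  tum <- make_variants(3, pos = c(100L, 200L, 300L))
  nor <- make_variants(1, pos = 200L)
  som <- subtract_germline(tum, nor)
  expect_equal(som$pos, c(100L, 300L))
  # union of somatic and shared keys recovers the tumour set disjointly
  shared <- tum[variant_key(tum) %in% variant_key(nor), ]
  expect_setequal(c(variant_key(som), variant_key(shared)),
                  variant_key(tum))
  expect_length(intersect(variant_key(som), variant_key(shared)), 0)

  expect_equal(nrow(subtract_germline(tum, make_variants(0)[0, ])), 3)
  expect_equal(nrow(subtract_germline(nor, tum)), 0)
})

test_that("germline SNP filters accept het and hom frequency windows", {
  het <- make_variants(1, alt_reads = 45L, total_reads = 100L)
  expect_true(pass_germline_snp_filters(het)$passed)
  hom <- make_variants(1, alt_reads = 95L, total_reads = 100L)
  expect_true(pass_germline_snp_filters(hom)$passed)
  mid <- make_variants(1, alt_reads = 70L, total_reads = 100L)
  d <- pass_germline_snp_filters(mid)
  expect_false(d$passed)
  expect_match(d$failed_rules, "genotype_frequency")
  # window boundaries are inclusive; hom boundary is strict
  expect_true(pass_germline_snp_filters(
    make_variants(1, alt_reads = 40L, total_reads = 100L))$passed)
  expect_true(pass_germline_snp_filters(
    make_variants(1, alt_reads = 60L, total_reads = 100L))$passed)
  expect_false(pass_germline_snp_filters(
    make_variants(1, alt_reads = 90L, total_reads = 100L))$passed)
})

test_that("damaging rule combines truncations and predictor consensus", {
  stopgain <- make_variants(1, effect = "stopgain")
  expect_true(is_damaging(stopgain))

  four_of_five <- make_variants(1, sift = "damaging",
                                polyphen2 = "damaging",
                                mutation_taster = "damaging",
                                mutation_assessor = "damaging",
                                lrt = "benign")
  expect_true(is_damaging(four_of_five))

  three_of_five <- make_variants(1, sift = "damaging",
                                 polyphen2 = "damaging",
                                 mutation_taster = "damaging")
  expect_false(is_damaging(three_of_five))
  # missing calls count as non-damaging votes by default...
  four_missing_one <- make_variants(1, sift = "damaging",
                                    polyphen2 = "damaging",
                                    mutation_taster = "damaging",
                                    mutation_assessor = "damaging")
  expect_true(is_damaging(four_missing_one))
  # ...but abstention mode shrinks the denominator
  expect_true(is_damaging(three_of_five, missing_as_abstention = TRUE))
  # synonymous variants never qualify through predictors
  syn <- make_variants(1, effect = "synonymous", sift = "damaging",
                       polyphen2 = "damaging", mutation_taster = "damaging",
                       mutation_assessor = "damaging", lrt = "damaging")
  expect_false(is_damaging(syn))
})

test_that("rarity rule treats missing panels as rare", {
  expect_true(is_rare(make_variants(1)))
  expect_true(is_rare(make_variants(1, maf_1000g = 0.005, maf_esp = 0.009)))
  expect_false(is_rare(make_variants(1, maf_1000g = 0.02)))
  expect_false(is_rare(make_variants(1, maf_esp = 0.01)))  # strict <
})

test_that("cohort artifact filter removes common panel-absent keys", {
  # 60 / 100 pooled carriers, absent from panels -> removed
  carriers <- c(rep(list("k1"), 60), rep(list(character(0)), 40))
  cohorts <- list(c1 = carriers[1:50], c2 = carriers[51:100])
  expect_false("k1" %in% cohort_artifact_filter(
    cohorts, panel_presence = c(k1 = FALSE)))

  # exactly 50 / 100 -> retained (strict inequality)
  carriers <- c(rep(list("k1"), 50), rep(list(character(0)), 50))
  cohorts <- list(c1 = carriers[1:50], c2 = carriers[51:100])
  expect_true("k1" %in% cohort_artifact_filter(
    cohorts, panel_presence = c(k1 = FALSE)))

  # panel-detected keys are exempt however common
  carriers <- c(rep(list("k1"), 90), rep(list(character(0)), 10))
  cohorts <- list(c1 = carriers[1:50], c2 = carriers[51:100])
  expect_true("k1" %in% cohort_artifact_filter(
    cohorts, panel_presence = c(k1 = TRUE)))

  # per-cohort mode removes only when every cohort exceeds the fraction
  cohorts <- list(c1 = rep(list("k1"), 10),
                  c2 = rep(list(character(0)), 10))
  expect_true("k1" %in% cohort_artifact_filter(
    cohorts, panel_presence = c(k1 = FALSE), mode = "per_cohort"))

  expect_error(cohort_artifact_filter(list(), c(k = TRUE)), "cohort")
})

test_that("filter composition is order-independent", {
  set.seed(42)
  n <- 50
  fp <- round(runif(n, 0, 1), 3)
  v <- make_variants(n,
    alt_reads = as.integer(sample(0:60, n, replace = TRUE)),
    total_reads = 100L,
    frac_plus = fp, frac_minus = 1 - fp)
  d <- pass_tumour_filters(v)
  # re-derive the pass set applying rules in a different order
  f <- allele_frequency(v)
  manual <- (pmin(v$frac_plus, v$frac_minus) >= 0.01) &
    (f >= 0.05) & (v$alt_reads >= 10)
  expect_equal(d$passed, manual)
})

test_that("filter chain recovers exactly a planted rare damaging set", {
  planted <- make_variants(3, pos = c(10L, 20L, 30L),
    effect = c("stopgain", "nonsynonymous", "nonsynonymous"),
    alt_reads = c(50L, 45L, 95L), total_reads = 100L,
    sift = c(NA, "damaging", "damaging"),
    polyphen2 = c(NA, "damaging", "damaging"),
    mutation_taster = c(NA, "damaging", "damaging"),
    mutation_assessor = c(NA, "damaging", "damaging"),
    maf_1000g = c(NA, 0.005, NA))
  decoys <- make_variants(4, pos = c(40L, 50L, 60L, 70L),
    effect = c("nonsynonymous", "synonymous", "stopgain", "nonsynonymous"),
    alt_reads = c(45L, 50L, 70L, 45L), total_reads = 100L,
    sift = c("damaging", "damaging", NA, "damaging"),
    polyphen2 = c("damaging", "damaging", NA, "damaging"),
    mutation_taster = c("damaging", "damaging", NA, "damaging"),
    mutation_assessor = c("benign", "damaging", NA, "damaging"),
    maf_1000g = c(NA, NA, NA, 0.05))
  # decoy 1: only 3/5 damaging; decoy 2: synonymous; decoy 3: f = 0.70
  # outside genotype windows; decoy 4: common in the population
  all_v <- variant_table(rbind(as.data.frame(planted),
                               as.data.frame(decoys)))
  recovered <- rare_damaging_snps(all_v)
  expect_setequal(variant_key(recovered), variant_key(planted))
})
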