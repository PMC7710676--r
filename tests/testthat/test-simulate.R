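test_that("simulator config validates planted effects", {
  expect_error(sim_config(planted_sets = data.frame(
    set_id = "GENE001", risk_ratio = 0.5, case_carrier_freq = 0.01)),
    ">= 1")
  expect_error(sim_config(miss_rate = 1.5), "rates")
  cfg <- sim_config(n_case = 50, n_ctrl = 50, n_sets = 2,
                    planted_sets = data.frame(set_id = "GENE001",
                                              risk_ratio = 1,
                                              case_carrier_freq = 0.01))
  dat <- simulate_cohort_data(cfg)
  # risk ratio 1 everywhere -> truth is effectively null
  expect_true(all(dat$truth$risk_ratio == 1))
})

test_that("same seed gives byte-identical outputs that re-parse", {
  cfg <- sim_config(seed = 77, n_case = 60, n_ctrl = 40, n_sets = 3,
                    variants_per_set = 8)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- simulate_cohort(cfg, d1)
  p2 <- simulate_cohort(cfg, d2)
  for (k in c("vcf", "samples", "map", "annotations", "truth"))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  g <- read_vcf(p1$vcf)
  expect_equal(dim(g), c(100L, 24L))
  s <- read_sample_table(p1$samples)
  expect_equal(sum(s$status), 60)
  m <- read_enhancer_map(p1$map)
  expect_length(m, 3)
  ann <- read_annotations(p1$annotations)
  g2 <- attach_annotations(g, ann)
  expect_equal(attr(g2, "unmatched"), 0L)
})

test_that("planted carrier frequencies land near expectation", {
  # target (RR = 12, case freq 0.0125) at 4,495/1,925 -> E[counts] ~ (56, 2)
  cfg <- sim_config(seed = 13, n_case = 4495, n_ctrl = 1925, n_sets = 1,
                    variants_per_set = 10, miss_rate = 0,
                    planted_sets = data.frame(set_id = "GENE001",
                                              risk_ratio = 12,
                                              case_carrier_freq = 0.0125))
  dat <- simulate_cohort_data(cfg)
  cs <- carrier_stats(dat$geno, dat$samples)
  # binomial bands: 56 +- 4*sd(7.4), 2 +- 4*sd(1.4)
  expect_true(cs$carriers_case >= 27 && cs$carriers_case <= 86)
  expect_true(cs$carriers_ctrl <= 8)
})

test_that("sample MAF converges to the spectrum mean (law of large numbers)", {
  cfg <- sim_config(seed = 29, n_case = 5000, n_ctrl = 5000, n_sets = 1,
                    variants_per_set = 60, miss_rate = 0)
  dat <- simulate_cohort_data(cfg)
  sample_maf <- mean(enhburden:::cohort_maf(dat$geno$dosages))
  spectrum_mean <- integrate(function(x)
    x * dbeta(x, 0.3, 80) /
      (pbeta(0.01, 0.3, 80) - pbeta(1e-4, 0.3, 80)),
    1e-4, 0.01)$value
  expect_equal(sample_maf, spectrum_mean, tolerance = 0.15)
})

test_that("null battery handles degenerate arguments", {
  cfg <- sim_config(seed = 3, n_case = 40, n_ctrl = 40, n_sets = 1,
                    variants_per_set = 5)
  empty <- null_pvalue_battery(cfg, 0)
  expect_equal(nrow(empty$table), 0)
  small <- null_pvalue_battery(cfg, 5, alpha = c(1.0, 0.05))
  expect_equal(small$table$fraction[small$table$alpha == 1], 1)
  planted <- sim_config(planted_sets = data.frame(
    set_id = "GENE001", risk_ratio = 5, case_carrier_freq = 0.01))
  expect_error(null_pvalue_battery(planted, 10), "all-null")
})
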