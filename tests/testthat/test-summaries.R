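test_that("carrier stats reproduce printed worked examples", {
  # 56 of 4,495 cases vs 2 of 1,925 controls -> risk ratio 12.0 (1 d.p.)
  build <- function(cc, n1, cu, n0) {
    d <- matrix(0, n1 + n0, 1)
    d[c(seq_len(cc), n1 + seq_len(cu)), 1] <- 1
    g <- toy_geno(d)
    carrier_stats(g, toy_samples(rep(c(1, 0), c(n1, n0))))
  }
  cs1 <- build(56, 4495, 2, 1925)
  expect_equal(round(cs1$risk_ratio, 1), 12.0)
  expect_equal(round(100 * cs1$carriers_case / cs1$n_case, 1), 1.2)
  cs2 <- build(15, 4495, 1, 1925)
  expect_equal(round(cs2$risk_ratio, 1), 6.4)
  expect_equal(round(100 * cs2$carriers_case / cs2$n_case, 1), 0.3)
  # equal carrier frequencies -> 1.0; zero control carriers -> undefined
  expect_equal(build(10, 100, 10, 100)$risk_ratio, 1.0)
  cs0 <- build(5, 100, 0, 100)
  expect_true(cs0$undefined && is.na(cs0$risk_ratio))
})

test_that("carrier stats ignore variant order and duplication", {
  set.seed(8)
  d <- matrix(rbinom(200 * 6, 2, 0.05), 200, 6)
  g <- toy_geno(d)
  samp <- toy_samples(rep(c(1, 0), 100))
  base <- carrier_stats(g, samp, 1:6)
  perm <- carrier_stats(g, samp, sample(1:6))
  dup <- carrier_stats(toy_geno(cbind(d, d[, 3])), samp, 1:7)
  expect_equal(perm$risk_ratio, base$risk_ratio)
  expect_equal(dup$carriers_case, base$carriers_case)
  expect_equal(dup$risk_ratio, base$risk_ratio)
})

test_that("inflation factors follow the genomic-control definitions", {
  # exact uniform grid quantiles -> lambda 1
  p <- (1:999) / 1000
  inf <- inflation(p, 4495, 1925)
  expect_equal(inf$lambda_obs, 1, tolerance = 1e-3)
  expect_equal(inf$lambda_1000, 1, tolerance = 1e-3)
  # lambda_obs = 1 is the fixed point of the rescaling at any n
  expect_equal(inflation(p, 100, 100)$lambda_1000, 1, tolerance = 1e-3)
  # inflated p-values rescale toward 1 for small cohorts
  p_inf <- pchisq(1.3 * qchisq(p, 1, lower.tail = FALSE), 1,
                  lower.tail = FALSE)
  i2 <- inflation(p_inf, 4495, 1925)
  expect_gt(i2$lambda_obs, 1.2)
  expect_lt(i2$lambda_1000 - 1, (i2$lambda_obs - 1))
  expect_error(inflation(c(0.5, 0), 10, 10), "\\(0, 1\\]")
  expect_error(inflation(0.5, 10, 10), "at least 2")
})

test_that("Q-Q points use rank/(n+1) expected quantiles", {
  qq1 <- qq_points(0.5)
  expect_equal(qq1$expected, -log10(0.5), tolerance = 1e-12)
  expect_equal(qq1$observed, -log10(0.5), tolerance = 1e-12)
  grid <- (1:99) / 100
  qq <- qq_points(grid)
  expect_lt(max(abs(qq$expected - qq$observed)), 0.01)
  # one strong signal among nulls lands above the diagonal at the top
  qs <- qq_points(c(1e-8, grid))
  top <- which.max(qs$observed)
  expect_gt(qs$observed[top], qs$expected[top])
})

test_that("multiple-testing adjustment matches hand enumeration", {
  res <- data.frame(p = c(0.01, 0.04, 0.03, 0.005))
  out <- adjust_multiple(res)
  expect_equal(out$p_bonf, pmin(res$p * 4, 1))
  expect_equal(out$q_bh, c(0.02, 0.04, 0.04, 0.02))  # step-up by hand
  one <- adjust_multiple(data.frame(p = 0.2))
  expect_equal(one$p_bonf, 0.2)
  expect_equal(one$q_bh, 0.2)
  two <- adjust_multiple(data.frame(p = c(0.01, 0.02)))
  expect_equal(two$p_bonf, c(0.02, 0.04))
})
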