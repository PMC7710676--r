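test_that("beta weights evaluate the Beta density", {
  expect_equal(beta_weight(0.37, 1, 1), 1.0)
  expect_equal(beta_weight(0.001, 1, 25), 25 * 0.999^24, tolerance = 1e-12)
  # cross-check by numerical integration of the density to 1
  expect_equal(integrate(function(p) beta_weight(p, 1, 25), 0, 1)$value, 1,
               tolerance = 1e-6)
  expect_lt(beta_weight(0.5, 1, 250), 1e-70)  # common variants ~ no weight
  expect_error(beta_weight(0, 1, 25), "inside")
})

test_that("null model reproduces closed-form and brute-force fits", {
  samp <- toy_samples(rep(c(1, 0), c(30, 70)))
  null <- fit_null(samp, covariates = character())
  expect_equal(unname(null$mu), rep(0.30, 100))
  expect_lt(abs(sum(null$res)), 1e-8)
  # constant covariate dropped with warning
  samp$flat <- 1
  expect_warning(fit_null(samp, covariates = "flat"), "constant")
  # balanced antisymmetric covariate -> intercept 0; oracle = direct
  # likelihood maximization on the 4-sample instance
  s4 <- toy_samples(c(1, 0, 1, 0))
  s4$z <- c(1, 1, -1, -1)
  null4 <- fit_null(s4, covariates = "z")
  negll <- function(b) -sum(s4$status * (b[1] + b[2] * s4$z) -
                              log1p(exp(b[1] + b[2] * s4$z)))
  oracle <- optim(c(0, 0), negll, method = "BFGS",
                  control = list(reltol = 1e-14))$par
  expect_equal(unname(null4$alpha_hat[1]), 0, tolerance = 1e-6)
  expect_equal(unname(null4$alpha_hat), oracle, tolerance = 1e-5)
  expect_error(fit_null(toy_samples(rep(1, 5))), "cases and controls")
})

test_that("skat_q matches direct arithmetic and the dense-matrix oracle", {
  samp <- toy_samples(c(1, 1, 0, 0))
  null <- fit_null(samp, covariates = character())
  # one variant, unit weight: r = (.5,.5,-.5,-.5), Q = (g'r)^2 = 0.25
  sq <- skat_q(matrix(c(1, 0, 0, 0), 4, 1), 1, null)
  expect_equal(sq$q, 0.25)
  # duplicated column doubles the score contribution; dense oracle
  set.seed(2)
  co <- toy_cohort(n_case = 50, n_ctrl = 50, m = 4, covariates = FALSE)
  null2 <- fit_null(co$samples, covariates = character())
  w <- c(1.5, 2, 0.5, 1)
  sq1 <- skat_q(co$G, w, null2)
  expect_equal(sq1$q, oracle_skat_q(co$G, w, null2$res), tolerance = 1e-10)
  Gdup <- cbind(co$G, co$G[, 1])
  sqd <- skat_q(Gdup, c(w, w[1]), null2)
  expect_equal(sqd$q, oracle_skat_q(Gdup, c(w, w[1]), null2$res),
               tolerance = 1e-10)
  s1 <- drop(crossprod(co$G[, 1] * w[1], null2$res))
  expect_equal(sqd$q, sq1$q + s1^2, tolerance = 1e-10)
  # all-zero weights give Q = 0; all-zero dosages are degenerate
  expect_equal(skat_q(co$G, rep(0, 4), null2)$q, 0)
  expect_error(skat_q(matrix(0, 100, 2), c(1, 1), null2), "degenerate")
})

test_that("SKAT-O degenerates to SKAT and burden at the grid ends", {
  set.seed(4)
  co <- toy_cohort(n_case = 200, n_ctrl = 200, m = 8)
  null <- fit_null(co$samples)
  w <- beta_weight(pmax(enhburden:::cohort_maf(co$G), 1e-4), 1, 25)
  expect_equal(skato_p(co$G, w, null, skato_config(0))$p,
               skat_p(co$G, w, null)$p, tolerance = 1e-10)
  # grid {1}: weighted burden score test, checked against its 1-df form
  spec <- skat_q(co$G, w, null)
  burden_var <- sum(enhburden:::project_kernel(null, co$G %*% w))
  p_burden <- pchisq(spec$q_burden / burden_var, 1, lower.tail = FALSE)
  expect_equal(skato_p(co$G, w, null, skato_config(1))$p, p_burden,
               tolerance = 1e-6)
  full <- skato_p(co$G, w, null)
  expect_true(full$p >= min(full$p_each) && full$p <= 1)
  expect_true(full$rho_min %in% skato_config()$rho_grid)
})

test_that("SKAT-O p-values are uniform under the null", {
  cfg <- sim_config(seed = 23, n_case = 250, n_ctrl = 250, n_sets = 1,
                    variants_per_set = 12, miss_rate = 0)
  bat <- null_pvalue_battery(cfg, n_replicates = 250)
  ks <- suppressWarnings(ks.test(bat$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a2 selection follows minimum p with ties to the smallest value", {
  tab <- data.frame(a2 = c(25, 250, 2500), p = c(0.2, 0.003, 0.01))
  expect_equal(select_a2(tab), 250)
  expect_equal(select_a2(data.frame(a2 = c(25, 250), p = c(0.5, 0.5))), 25)
  expect_equal(select_a2(data.frame(a2 = 2500, p = 0.9)), 2500)
})

test_that("tune_a2 runs the grid on genotypes and returns the argmin", {
  set.seed(31)
  co <- toy_cohort(n_case = 300, n_ctrl = 300, m = 10,
                   maf = rep(0.005, 10))
  # plant carriers in cases so some a2 is informative
  co$G[1:25, 1] <- 1
  null <- fit_null(co$samples)
  out <- tune_a2(co$G, null, grid = c(25, 250))
  expect_equal(nrow(out$table), 2)
  expect_equal(out$a2, out$table$a2[which.min(out$table$p)])
  out1 <- tune_a2(co$G, null, grid = 250)
  expect_equal(out1$a2, 250)
  expect_error(tune_a2(co$G[, 0], null), "degenerate")
})
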