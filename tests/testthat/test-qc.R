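test_that("sample QC removes >10% missingness with strict boundary", {
  d <- matrix(0, 4, 20)
  d[1, 1:3] <- NA   # 15% missing -> excluded
  d[2, 1:2] <- NA   # exactly 10% -> retained
  d[, 20] <- 1      # keep matrix polymorphic
  g <- toy_geno(d)
  out <- qc_samples(g, toy_samples(c(1, 1, 0, 0)))
  expect_equal(out$report$excluded_samples$sample_id, "s001")
  expect_equal(out$report$excluded_samples$reason, "missingness")
  expect_equal(nrow(out$geno$dosages), 3)
  expect_error(qc_samples(toy_geno(matrix(NA_real_, 2, 4)),
                          toy_samples(c(1, 0))), "empty cohort")
})

test_that("variant QC applies missingness, HWE, monomorphic rules in order", {
  n <- 100
  status <- rep(c(1, 0), each = n / 2)
  d <- matrix(rep(c(0, 1), n / 2), n, 4)  # het-ish baseline, polymorphic
  d[1:6, 1] <- NA                         # 6% missing -> removed
  d[, 2] <- 0                             # monomorphic -> removed
  # column 3: perfect HWE in controls (AA=12, Aa=26, aa=12)
  d[51:100, 3] <- c(rep(0, 12), rep(1, 26), rep(2, 12))
  # column 4: extreme het excess in controls -> HWE kill
  d[51:100, 4] <- rep(1, 50)
  d[1:50, 3:4] <- rep(c(0, 1), 25)
  g <- toy_geno(d)
  out <- qc_variants(g, toy_samples(status))
  rep_ <- out$report$excluded_variants
  expect_setequal(rep_$reason[match(g$variants$key[c(1, 2, 4)], rep_$key)],
                  c("missingness", "monomorphic", "hwe"))
  expect_false(g$variants$key[3] %in% rep_$key)
  expect_equal(ncol(out$geno$dosages), 1)
  # counts sum to total excluded
  expect_equal(sum(out$report$counts), nrow(rep_))
})

test_that("variant QC flags depth outliers and differential missingness", {
  n <- 200
  status <- rep(c(1, 0), each = n / 2)
  set.seed(1)
  d <- matrix(rbinom(n * 3, 1, 0.3), n, 3)
  d[1:40, 2] <- NA  # 40 missing cases vs 0 controls -> differential
  depth <- c(40, 41, 400)  # third is a gross outlier... but sd is inflated
  g <- toy_geno(d, mean_depth = depth)
  out <- qc_variants(g, toy_samples(status),
                     thresholds = list(variant_miss_max = 0.5,
                                       depth_sd_max = 1))
  rep_ <- out$report$excluded_variants
  expect_equal(rep_$reason[rep_$key == g$variants$key[2]], "diff_missingness")
  expect_equal(rep_$reason[rep_$key == g$variants$key[3]], "depth")
})

test_that("QC is idempotent on its own output", {
  set.seed(3)
  d <- matrix(rbinom(600, 2, 0.3), 30, 20)
  d[sample(length(d), 30)] <- NA
  g <- toy_geno(d)
  samp <- toy_samples(rep(c(1, 0), 15))
  once <- qc_variants(qc_samples(g, samp)$geno, samp)
  twice <- qc_variants(once$geno, samp)
  expect_equal(twice$geno$dosages, once$geno$dosages)
  expect_equal(nrow(twice$report$excluded_variants), 0)
})

test_that("HWE exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_p(25, 50, 25), 1.0, tolerance = 1e-12)
  expect_equal(hwe_exact_p(0, 0, 10), 1.0)
  expect_lt(hwe_exact_p(50, 0, 50), 1e-25)
  expect_error(hwe_exact_p(0, 0, 0), "all genotype counts zero")
  set.seed(11)
  for (rep in 1:40) {
    N <- sample(2:100, 1)          # up to 200 alleles
    n_aa <- sample(0:N, 1)
    n_Aa <- sample(0:(N - n_aa), 1)
    n_AA <- N - n_aa - n_Aa
    expect_equal(hwe_exact_p(n_AA, n_Aa, n_aa),
                 oracle_hwe(n_AA, n_Aa, n_aa), tolerance = 1e-9)
  }
})

test_that("differential missingness is the two-sided Fisher exact test", {
  expect_equal(differential_missingness_p(5, 100, 5, 100), 1.0)
  expect_equal(differential_missingness_p(0, 10, 0, 10), 1.0)
  # two-sided hypergeometric enumeration oracle
  oracle_fisher <- function(mc, nc, mu, nu) {
    tot <- mc + mu
    ks <- max(0, tot - nu):min(tot, nc)
    probs <- dhyper(ks, nc, nu, tot)
    obs <- probs[match(mc, ks)]
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  for (tab in list(c(10, 100, 0, 100), c(3, 40, 9, 60), c(1, 12, 6, 8))) {
    expect_equal(differential_missingness_p(tab[1], tab[2], tab[3], tab[4]),
                 oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-7)
  }
  expect_lt(differential_missingness_p(10, 100, 0, 100), 0.01)
  expect_error(differential_missingness_p(0, 0, 1, 10), "empty class")
})
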