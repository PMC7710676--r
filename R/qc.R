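# Sample- and variant-level quality control.
#
# Thresholds follow the conventions of large case-control WGS cohorts:
# sample genotype missingness > 10% excluded; variant missingness > 5%,
# Hardy-Weinberg disequilibrium in controls at p < 1e-6, differential
# case/control missingness at p < 1e-6, mean depth more than 6 s.d. from the
# cohort mean, and monomorphic variants removed.  All comparators are strict
# on the "bad" side.  Every exclusion gets exactly one primary reason code
# (the first failing rule in the order above).

qc_defaults <- function() {
  list(sample_miss_max = 0.10,
       variant_miss_max = 0.05,
       hwe_p_min = 1e-6,
       diffmiss_p_min = 1e-6,
       depth_sd_max = 6)
}

qc_report <- function(excluded_samples, excluded_variants, warnings = character()) {
  counts <- c(table(excluded_samples$reason), table(excluded_variants$reason))
  structure(list(excluded_samples = excluded_samples,
                 excluded_variants = excluded_variants,
                 counts = counts, warnings = warnings),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$excluded_samples), "samples and",
      nrow(x$excluded_variants), "variants excluded\n")
  if (length(x$counts))
    for (i in seq_along(x$counts))
      cat(sprintf("  %s: %d\n", names(x$counts)[i], x$counts[i]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Sample-level quality control
#'
#' Excludes samples whose genotype missingness exceeds the threshold
#' (default 10%, strict `>`; a sample at exactly the threshold is retained).
#'
#' @param geno a [genotype_matrix()].
#' @param samples sample table (see [read_sample_table()]).
#' @param thresholds list overriding [qc_defaults()].
#' @return list with elements `geno` (filtered), `samples` (filtered) and
#'   `report` (a `qc_report`).
#' @export
qc_samples <- function(geno, samples, thresholds = qc_defaults()) {
  if (ncol(geno$dosages) == 0) enh_data_error("empty genotype matrix")
  th <- modifyList(qc_defaults(), thresholds)
  miss <- rowMeans(is.na(geno$dosages))
  bad <- miss > th$sample_miss_max
  if (all(bad)) enh_data_error("all samples removed by QC (empty cohort)")
  excl <- data.frame(sample_id = geno$sample_ids[bad],
                     reason = rep("missingness", sum(bad)),
                     value = miss[bad], stringsAsFactors = FALSE)
  rep <- qc_report(excl, data.frame(key = character(), reason = character(),
                                    value = numeric()))
  list(geno = subset_geno(geno, samples = !bad),
       samples = samples[match(geno$sample_ids[!bad], samples$sample_id), ],
       report = rep)
}

#' Variant-level quality control
#'
#' Applies, in order: missingness > 5%; Hardy-Weinberg exact test in controls
#' (removed if p < 1e-6); differential case/control missingness by Fisher's
#' exact test (removed if p < 1e-6); mean depth beyond 6 s.d. of the cohort
#' depth distribution (skipped when depth is absent); monomorphic removal.
#'
#' @inheritParams qc_samples
#' @return list with `geno` (filtered) and `report`.
#' @export
qc_variants <- function(geno, samples, thresholds = qc_defaults()) {
  th <- modifyList(qc_defaults(), thresholds)
  warn <- character()
  samples <- samples[match(geno$sample_ids, samples$sample_id), ]
  is_case <- samples$status == 1
  d <- geno$dosages
  m <- ncol(d)
  reason <- rep(NA_character_, m)
  value <- rep(NA_real_, m)

  miss <- colMeans(is.na(d))
  hit <- miss > th$variant_miss_max
  reason[hit] <- "missingness"; value[hit] <- miss[hit]

  if (!any(!is_case)) {
    warn <- c(warn, "no control samples: HWE stage skipped")
  } else {
    ctrl <- d[!is_case, , drop = FALSE]
    for (j in which(is.na(reason))) {
      g <- ctrl[, j]
      n0 <- sum(g == 0, na.rm = TRUE)
      n1 <- sum(g == 1, na.rm = TRUE)
      n2 <- sum(g == 2, na.rm = TRUE)
      if (n0 + n1 + n2 == 0) next
      p <- hwe_exact_p(n0, n1, n2)
      if (p < th$hwe_p_min) { reason[j] <- "hwe"; value[j] <- p }
    }
  }

  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  if (n_case > 0 && n_ctrl > 0) {
    for (j in which(is.na(reason))) {
      mc <- sum(is.na(d[is_case, j])); mu <- sum(is.na(d[!is_case, j]))
      if (mc + mu == 0) next
      p <- differential_missingness_p(mc, n_case, mu, n_ctrl)
      if (p < th$diffmiss_p_min) { reason[j] <- "diff_missingness"; value[j] <- p }
    }
  }

  depth <- geno$variants$mean_depth
  if (all(is.na(depth))) {
    warn <- c(warn, "mean depth absent: depth stage skipped")
  } else {
    mu <- mean(depth, na.rm = TRUE); s <- sd(depth, na.rm = TRUE)
    if (is.finite(s) && s > 0) {
      dev <- abs(depth - mu) / s
      hit <- !is.na(dev) & dev > th$depth_sd_max & is.na(reason)
      reason[hit] <- "depth"; value[hit] <- dev[hit]
    }
  }

  for (j in which(is.na(reason))) {
    g <- d[, j]
    ac <- sum(g, na.rm = TRUE)
    an <- 2 * sum(!is.na(g))
    if (an == 0 || ac == 0 || ac == an) { reason[j] <- "monomorphic"; value[j] <- ac }
  }

  bad <- !is.na(reason)
  excl <- data.frame(key = geno$variants$key[bad], reason = reason[bad],
                     value = value[bad], stringsAsFactors = FALSE)
  rep <- qc_report(data.frame(sample_id = character(), reason = character(),
                              value = numeric()), excl, warnings = warn)
  list(geno = subset_geno(geno, variants = !bad), report = rep)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test (sum of probabilities of all heterozygote
#' configurations no more probable than the observed one, conditional on the
#' allele counts).  The chi-square approximation is invalid at rare-variant
#' counts, so the exact test is used for QC.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  N <- n_AA + n_Aa + n_aa
  if (N == 0) enh_data_error("hwe_exact_p: all genotype counts zero")
  if (n_AA < n_aa) { tmp <- n_AA; n_AA <- n_aa; n_aa <- tmp }  # orient to minor
  n <- n_Aa + 2 * n_aa
  # all het counts with the parity of n, het + 2*hom_minor = n
  h <- seq(n %% 2, min(n, 2 * N - n), by = 2)
  logw <- lfactorial(N) - lfactorial((n - h) / 2) - lfactorial(h) -
    lfactorial(N - (n + h) / 2) + h * log(2)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  obs <- w[match(n_Aa, h)]
  min(1, sum(w[w <= obs * (1 + 1e-12)]))
}

#' Differential missingness test
#'
#' Two-sided Fisher exact test on the 2x2 (missing vs called) x (case vs
#' control) table.
#'
#' @param miss_case,n_case missing calls and total samples among cases.
#' @param miss_ctrl,n_ctrl likewise among controls.
#' @return p-value in (0, 1].
#' @export
differential_missingness_p <- function(miss_case, n_case, miss_ctrl, n_ctrl) {
  if (n_case <= 0 || n_ctrl <= 0)
    enh_data_error("differential_missingness_p: empty class")
  stopifnot(miss_case <= n_case, miss_ctrl <= n_ctrl)
  tab <- matrix(c(miss_case, n_case - miss_case,
                  miss_ctrl, n_ctrl - miss_ctrl), nrow = 2)
  fisher.test(tab)$p.value
}
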