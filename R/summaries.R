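# Carrier counts, risk ratios, genomic inflation, Q-Q tables and
# multiple-testing adjustment.

#' Carrier counts and risk ratio for a variant set
#'
#' A carrier is a sample with dosage >= 1 at one or more retained variants of
#' the set (missing calls do not count).  The risk ratio is the case carrier
#' frequency divided by the control carrier frequency; when no control
#' carries a variant the ratio is undefined (`NA` with `undefined = TRUE`).
#'
#' @param geno a [genotype_matrix()].
#' @param samples sample table aligned to `geno` (matched by `sample_id`).
#' @param variant_idx indices of the set's retained variants.
#' @return list: `carriers_case`, `carriers_ctrl`, `n_case`, `n_ctrl`,
#'   `risk_ratio`, `undefined`.
#' @export
carrier_stats <- function(geno, samples, variant_idx = seq_len(ncol(geno$dosages))) {
  samples <- samples[match(geno$sample_ids, samples$sample_id), ]
  is_case <- samples$status == 1
  d <- geno$dosages[, variant_idx, drop = FALSE]
  carrier <- rowSums(d >= 1, na.rm = TRUE) > 0
  cc <- sum(carrier & is_case)
  cu <- sum(carrier & !is_case)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  undefined <- cu == 0
  rr <- if (undefined) NA_real_ else (cc / n1) / (cu / n0)
  list(carriers_case = cc, carriers_ctrl = cu, n_case = n1, n_ctrl = n0,
       risk_ratio = rr, undefined = undefined)
}

# the plain frequency-ratio definition, exposed for worked examples
risk_ratio <- function(carriers_case, n_case, carriers_ctrl, n_ctrl) {
  if (carriers_ctrl == 0) return(NA_real_)
  (carriers_case / n_case) / (carriers_ctrl / n_ctrl)
}

CHISQ1_MEDIAN <- 0.4549364  # median of the 1-df chi-square

#' Genomic-control inflation factors
#'
#' `lambda_obs` is the median of the chi-square-transformed p-values divided
#' by the 1-df chi-square median (0.4549364); `lambda_1000` rescales it to an
#' equivalent 1,000-case / 1,000-control study:
#' `1 + (lambda_obs - 1) * (1/n_case + 1/n_ctrl) / (2/1000)`.
#'
#' @param p vector of p-values in (0, 1], length >= 2.
#' @param n_case,n_ctrl cohort sizes.
#' @return list of class `inflation_stats`: `lambda_obs`, `lambda_1000`,
#'   `n_case`, `n_ctrl`.
#' @export
inflation <- function(p, n_case, n_ctrl) {
  if (length(p) < 2) enh_data_error("need at least 2 p-values")
  if (any(p <= 0 | p > 1)) enh_data_error("p-values must lie in (0, 1]")
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda_obs <- median(chi) / CHISQ1_MEDIAN
  lambda_1000 <- 1 + (lambda_obs - 1) *
    (1 / n_case + 1 / n_ctrl) / (1 / 1000 + 1 / 1000)
  structure(list(lambda_obs = lambda_obs, lambda_1000 = lambda_1000,
                 n_case = n_case, n_ctrl = n_ctrl),
            class = "inflation_stats")
}

#' @export
print.inflation_stats <- function(x, ...) {
  cat(sprintf("lambda_GC = %.3f, lambda_1000 = %.3f (n = %d cases / %d controls)\n",
              x$lambda_obs, x$lambda_1000, x$n_case, x$n_ctrl))
  invisible(x)
}

#' Q-Q plot table
#'
#' Observed p-values sorted ascending; expected quantiles `rank / (n + 1)`;
#' both returned on the -log10 scale.
#'
#' @param p vector of p-values.
#' @return data.frame with `expected` and `observed` (-log10 scale).
#' @export
qq_points <- function(p) {
  stopifnot(length(p) >= 1)
  p <- sort(p)
  n <- length(p)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(p))
}

#' Multiple-testing adjustment
#'
#' Adds Bonferroni-adjusted p (`p * m`, clipped at 1) and Benjamini-Hochberg
#' q-values to a result table.
#'
#' @param results data.frame with a `p` column.
#' @return the table with `p_bonf` and `q_bh` columns.
#' @export
adjust_multiple <- function(results) {
  results$p_bonf <- p.adjust(results$p, method = "bonferroni")
  results$q_bh <- p.adjust(results$p, method = "BH")
  results
}
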