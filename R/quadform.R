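# Tail probabilities of Q = sum_i lambda_i * chisq_1.
#
# The survival function of a positive-definite quadratic form in standard
# normals is computed exactly by expanding the distribution as an infinite
# mixture of central chi-squares (Ruben's series): with 0 < beta <= min
# lambda,
#
#   P(Q <= q) = sum_{k>=0} a_k * P(chisq_{m + 2k} <= q / beta),
#
# where the mixing coefficients a_k are nonnegative and sum to one, so the
# truncation error after K terms is bounded by the unaccounted mass
# 1 - sum_{k<=K} a_k.  Coefficients follow the recursion
#   a_0 = prod (beta/lambda_i)^{1/2},
#   a_k = (1/(2k)) sum_{j<k} gamma_{k-j} a_j,   gamma_r = sum_i c_i^r,
# with c_i = 1 - beta/lambda_i in [0, 1).  beta = 0.90625 * min(lambda)
# (the classical choice) keeps all c_i < 1.
#
# Coefficients depend only on the eigenvalue set, so they are computed once
# (`quadform_coef`) and reused to evaluate the survival function at many
# quantiles — the SKAT-O combination integrates this CDF along a grid.
#
# When the eigenvalue spread makes the series converge too slowly (mass not
# captured within `max_terms`), we fall back to the Liu-Tang-Zhang
# four-moment noncentral-chi-square approximation and flag the result.

# SKAT-style eigenvalue cleaning: drop eigenvalues below mean(positive)/1e5
clean_lambda <- function(lambda, tol = 1e-5) {
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0) return(numeric(0))
  lambda[lambda >= mean(lambda) * tol]
}

quadform_coef <- function(lambda, acc = 1e-9, max_terms = 1e5,
                          chunk = 256L) {
  m <- length(lambda)
  stopifnot(m >= 1, all(lambda > 0))
  beta <- 0.90625 * min(lambda)
  c_i <- 1 - beta / lambda
  la0 <- 0.5 * sum(log(beta / lambda))
  if (la0 < log(.Machine$double.xmin) + 20) return(NULL)  # a_0 underflows
  a <- numeric(min(max_terms, 2^31 - 1))
  a[1] <- exp(la0)
  gam <- numeric(0)
  mass <- a[1]
  k <- 1L
  K <- length(a)
  while (1 - mass > acc && k < K) {
    if (k > length(gam)) {
      # extend the power sums gamma_r = sum c_i^r in chunks
      r <- seq(length(gam) + 1L, length(gam) + chunk)
      gam <- c(gam, vapply(r, function(rr) sum(c_i^rr), 0))
    }
    a[k + 1L] <- sum(gam[k:1] * a[1:k]) / (2 * k)
    mass <- mass + a[k + 1L]
    k <- k + 1L
  }
  if (1 - mass > acc) return(NULL)  # did not converge; caller falls back
  a <- a[1:k]
  df <- m + 2 * (0:(k - 1L))
  # drop negligible coefficients (cheaper evaluation); the discarded mass is
  # folded into the truncation bound, which stays <= acc
  keep <- a > (acc / (2 * k))
  if (sum(a[!keep]) < acc / 2) { a <- a[keep]; df <- df[keep] }
  list(beta = beta, a = a, df = df, mass = mass)
}

quadform_surv_coef <- function(q, coef) {
  # P(Q > q); truncation puts the answer within (0, 1 - mass] of the truth
  vapply(q, function(qq) {
    if (qq <= 0) return(1)
    min(1, max(0, sum(coef$a * pchisq(qq / coef$beta, df = coef$df,
                                      lower.tail = FALSE))))
  }, 0)
}

# Liu-Tang-Zhang four-moment match: approximate Q by a scaled noncentral
# chi-square matching skewness (and kurtosis when feasible).
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  list(l = l, delta = delta, muQ = c1, sigmaQ = sqrt(2 * c2))
}

liu_surv <- function(q, lambda) {
  pp <- liu_params(lambda)
  tstar <- (q - pp$muQ) / pp$sigmaQ
  x <- tstar * sqrt(2 * (pp$l + 2 * pp$delta)) + pp$l + pp$delta
  pchisq(x, df = pp$l, ncp = pp$delta, lower.tail = FALSE)
}

# Gauss-Legendre nodes/weights by Golub-Welsch (eigen of the Jacobi matrix),
# composited over panels; used for the smooth one-dimensional SKAT-O integral
gauss_legendre_panels <- function(breaks, n_nodes = 24L) {
  k <- seq_len(n_nodes - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n_nodes)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x01 <- e$values                      # nodes on [-1, 1]
  w01 <- 2 * e$vectors[1, ]^2
  xs <- ws <- numeric(0)
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; bb <- breaks[i + 1]
    xs <- c(xs, (bb - a) / 2 * x01 + (a + bb) / 2)
    ws <- c(ws, (bb - a) / 2 * w01)
  }
  list(x = xs, w = ws)
}

#' P-value of a mixture of one-degree chi-squares
#'
#' Computes `P(sum_i lambda_i chisq_1 > q)` exactly via a central
#' chi-square mixture series with a rigorous truncation bound (target
#' accuracy `acc`), falling back to a four-moment approximation (flagged)
#' when the series does not converge within `max_terms` terms.  The result
#' is clipped to (1e-300, 1].
#'
#' @param lambdas nonnegative eigenvalues of the null kernel (at least one
#'   positive; values negative beyond numerical tolerance are an error).
#' @param q observed statistic, `q >= 0`.
#' @param acc target absolute accuracy of the series (default 1e-9).
#' @param max_terms series length cap (default 1e5; inner SKAT-O calls use a
#'   smaller cap for speed).
#' @return list with `p`, `method` (`"series"` or `"liu"`), and `fallback`
#'   flag.
#' @export
pvalue_quadform <- function(lambdas, q, acc = 1e-9, max_terms = 1e5) {
  if (q < 0) enh_data_error("quadratic-form statistic must be >= 0")
  tol <- max(abs(lambdas)) * 1e-10
  if (any(lambdas < -tol))
    enh_data_error("negative eigenvalues beyond numerical tolerance")
  lam <- clean_lambda(lambdas)
  if (length(lam) == 0) enh_data_error("no positive eigenvalues")
  coef <- quadform_coef(lam, acc = acc, max_terms = max_terms)
  if (!is.null(coef)) {
    p <- quadform_surv_coef(q, coef)
    method <- "series"
  } else {
    p <- liu_surv(q, lam)
    method <- "liu"
  }
  list(p = min(1, max(1e-300, p)), method = method,
       fallback = identical(method, "liu"))
}
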