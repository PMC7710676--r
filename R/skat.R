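# SKAT and the optimal unified test (SKAT-O), from first principles.
#
# For a set of m variants with dosage matrix G (n x m), per-variant weights
# w_j, and null residuals r = y - mu from the covariate-adjusted logistic
# model, the variance-component score statistic is
#
#   Q_skat = r' GW W'G' r = sum_j (w_j g_j' r)^2,
#
# whose null distribution is a mixture of 1-df chi-squares with eigenvalues
# from the projected kernel W G' P G W, P = V - VX(X'VX)^-1 X'V.  The burden
# statistic collapses the weighted score first: Q_burden = (sum_j w_j g_j'r)^2.
# SKAT-O evaluates Q_rho = (1-rho) Q_skat + rho Q_burden over a rho grid,
# takes the minimum p-value, and converts it to a single p by integrating
# over the conditional null distribution of the common (burden) chi-square
# component (the one-dimensional integral of the optimal unified test).

#' Beta-density variant weight
#'
#' `w_j = Beta(p_j; a1, a2) = p_j^(a1-1) (1-p_j)^(a2-1) / B(a1, a2)`, the
#' standard device for upweighting rare variants in kernel association
#' tests.  With `a1 = 1` the weight decreases monotonically in MAF; larger
#' `a2` concentrates weight on ever rarer variants.
#'
#' @param p_j cohort minor allele frequency in (0, 1) (estimated from all
#'   cases and controls combined — distinct from the reference-panel AF used
#'   for filtering).
#' @param a1,a2 Beta shape parameters (>= 1).
#' @return weight vector, finite and positive.
#' @export
beta_weight <- function(p_j, a1 = 1, a2 = 25) {
  if (any(p_j <= 0 | p_j >= 1))
    enh_data_error("beta_weight: p_j must be inside (0, 1)")
  stopifnot(a1 >= 1, a2 >= 1)
  dbeta(p_j, a1, a2)
}

# cohort MAF from dosages (alt-allele frequency folded to minor)
cohort_maf <- function(dosages) {
  af <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

# mean-impute missing dosages per variant (reference-implementation
# convention; keeps Q well-defined)
impute_dosages <- function(G) {
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (any(miss)) G[miss, j] <- mean(G[!miss, j])
  }
  G
}

#' SKAT statistic and its null eigenvalues
#'
#' @param G n x m dosage matrix for the variants of one set (missing values
#'   mean-imputed per variant).
#' @param w per-variant weights (see [beta_weight()]).
#' @param null a fitted [fit_null()] model.
#' @return list of class `quadform_spec` with `q` (observed statistic),
#'   `lambdas` (eigenvalues, descending), plus `q_burden` and the projected
#'   kernel `A` reused by the SKAT-O combination.
#' @export
skat_q <- function(G, w, null) {
  G <- impute_dosages(as.matrix(G))
  stopifnot(length(w) == ncol(G), nrow(G) == length(null$res))
  if (all(apply(G, 2, function(g) length(unique(g)) == 1)))
    enh_data_error("degenerate set: zero-variance kernel")
  Gw <- G * rep(w, each = nrow(G))
  s <- drop(crossprod(Gw, null$res))
  A <- project_kernel(null, Gw)
  lambdas <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                  decreasing = TRUE)
  structure(list(q = sum(s^2), q_burden = sum(s)^2, score = s,
                 lambdas = lambdas, A = A),
            class = "quadform_spec")
}

#' SKAT p-value for one set
#'
#' @inheritParams skat_q
#' @param acc accuracy passed to [pvalue_quadform()].
#' @return list `p`, `q`, `fallback`.
#' @export
skat_p <- function(G, w, null, acc = 1e-9) {
  spec <- skat_q(G, w, null)
  pv <- pvalue_quadform(spec$lambdas, spec$q, acc = acc)
  list(p = pv$p, q = spec$q, fallback = pv$fallback)
}

#' SKAT-O configuration
#'
#' @param rho_grid mixing grid; must contain 0 (pure SKAT) and 1 (pure
#'   burden).  Default is the classical 8-point grid.
#' @export
skato_config <- function(rho_grid = c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2,
                                      0.5, 1)) {
  if (!(0 %in% rho_grid && 1 %in% rho_grid) && length(rho_grid) > 1)
    enh_config_error("rho grid must contain 0 and 1")
  if (any(rho_grid < 0 | rho_grid > 1))
    enh_config_error("rho values must lie in [0, 1]")
  structure(list(rho_grid = sort(unique(rho_grid))), class = "skato_config")
}

# symmetric square root of R_rho = (1-rho) I + rho 11'
# eigenvalues: 1 - rho + m*rho (on the 1 direction), 1 - rho elsewhere
rho_half_transform <- function(A, rho) {
  m <- ncol(A)
  s1 <- sqrt(1 - rho + m * rho)
  s2 <- sqrt(1 - rho)
  cfac <- (s1 - s2) / m
  # R^{1/2} = s2 I + cfac 11'
  rs <- rowSums(A); cs <- colSums(A); tot <- sum(A)
  B <- s2^2 * A +
    s2 * cfac * (matrix(rs, m, m) + matrix(cs, m, m, byrow = TRUE)) +
    cfac^2 * tot
  (B + t(B)) / 2
}

skato_each_rho <- function(spec, rho_grid, acc) {
  m <- length(spec$score)
  res <- lapply(rho_grid, function(rho) {
    qr_ <- (1 - rho) * spec$q + rho * spec$q_burden
    lam <- eigen(rho_half_transform(spec$A, rho), symmetric = TRUE,
                 only.values = TRUE)$values
    lam <- clean_lambda(lam)
    pv <- pvalue_quadform(lam, qr_, acc = acc, max_terms = 5000)
    list(rho = rho, q = qr_, lambda = lam, p = pv$p, fallback = pv$fallback)
  })
  res
}

#' SKAT-O optimal unified p-value
#'
#' Evaluates `Q_rho = (1 - rho) Q_skat + rho Q_burden` over the grid, takes
#' the minimum per-`rho` p-value and combines it into a single p-value by
#' one-dimensional integration over the conditional null of the minimum-p
#' statistic; the result is capped at `min-p * grid size` (Bonferroni) and
#' clipped to (1e-300, 1].
#'
#' @inheritParams skat_q
#' @param config a [skato_config()].
#' @param acc quadratic-form accuracy (per-`rho` p-values use `acc`; the
#'   integrand uses 1e-6 as in reference implementations).
#' @return list with `p`, `rho_min` (grid argmin, ties to the smallest rho),
#'   `p_each` (per-rho p-values), `n_variants`, `fallback`.
#' @export
skato_p <- function(G, w, null, config = skato_config(), acc = 1e-9) {
  spec <- skat_q(G, w, null)
  m <- length(spec$score)
  grid <- config$rho_grid
  if (m == 1) {
    # all rho coincide for a single variant
    pv <- pvalue_quadform(spec$lambdas, spec$q, acc = acc)
    return(list(p = pv$p, rho_min = grid[1], p_each = rep(pv$p, length(grid)),
                n_variants = 1L, q = spec$q, fallback = pv$fallback))
  }
  each <- skato_each_rho(spec, grid, acc)
  p_each <- vapply(each, `[[`, 0, "p")
  fallback <- any(vapply(each, `[[`, NA, "fallback"))
  pmin_ <- min(p_each)
  rho_min <- grid[which.min(p_each)]  # which.min takes the first = smallest rho
  if (length(grid) == 1)
    return(list(p = p_each[1], rho_min = grid[1], p_each = p_each,
                n_variants = m, q = spec$q, fallback = fallback))

  # decomposition quantities from the kernel A = Z'Z (Z = P^{1/2} G W):
  # zbar = Z 1 / m; cof_j = zbar'Z_j / |zbar|^2; Z_C = Z - zbar cof'
  A <- spec$A
  u <- rowSums(A) / m                  # Z' zbar
  zb2 <- sum(A) / m^2                  # |zbar|^2
  if (zb2 <= 0) {
    # burden direction degenerate; fall back to plain SKAT
    pv <- pvalue_quadform(spec$lambdas, spec$q, acc = acc)
    return(list(p = pv$p, rho_min = 0, p_each = p_each, n_variants = m,
                q = spec$q, fallback = pv$fallback))
  }
  cof <- u / zb2
  Acc_ <- A - outer(cof, u) - outer(u, cof) + outer(cof, cof) * zb2
  lam_c <- clean_lambda(eigen((Acc_ + t(Acc_)) / 2, symmetric = TRUE,
                              only.values = TRUE)$values)
  W31 <- outer(cof, cof) * zb2         # Z_M' Z_M
  var_remain <- 4 * sum(W31 * Acc_)
  mu_q <- sum(lam_c)
  var_q <- 2 * sum(lam_c^2) + var_remain
  grid_c <- pmin(grid, 0.999)          # avoid division by 1 - rho = 0
  tau <- zb2 * (m^2 * grid_c + (1 - grid_c) * sum(cof^2))

  # per-rho quantile of the min-p under each rho's moments (Liu scale)
  qmin <- vapply(each, function(e) {
    pp <- liu_params(e$lambda)
    df <- max(pp$l, 1e-8)
    q0 <- qchisq(pmin_, df = df, lower.tail = FALSE)
    (q0 - df) / sqrt(2 * df) * pp$sigmaQ + pp$muQ
  }, 0)

  coef_c <- if (length(lam_c)) quadform_coef(lam_c, acc = 1e-7,
                                             max_terms = 5000) else NULL
  sd1 <- sqrt(max(var_q - var_remain, 0)) / sqrt(var_q)
  cond_cdf <- function(x) {
    # P(remainder mixture <= conditional threshold | burden chi-square = x)
    qx <- vapply(x, function(xx)
      min((qmin - tau * xx) / (1 - grid_c)), 0)
    qs <- (qx - mu_q) * sd1 + mu_q
    surv <- if (!is.null(coef_c)) quadform_surv_coef(qs, coef_c)
            else if (length(lam_c)) liu_surv(qs, lam_c)
            else as.numeric(qs < 0)
    1 - surv
  }
  # E[cond_cdf(chisq_1)] via the substitution x = y^2 (removes the density
  # singularity at 0), fixed Gauss-Legendre panels on y in (0, 8)
  int <- tryCatch({
    gl <- gauss_legendre_panels(c(0, 1, 2.5, 8), 24L)
    sum(gl$w * 2 * stats::dnorm(gl$x) * cond_cdf(gl$x^2))
  }, error = function(e) NA_real_)
  p <- if (is.na(int)) pmin_ * length(grid) else 1 - int
  p <- min(p, pmin_ * length(grid))
  p <- min(1, max(p, 1e-300))
  list(p = p, rho_min = rho_min, p_each = p_each, n_variants = m,
       q = spec$q, fallback = fallback)
}

#' Select the rarity-weight shape parameter on a positive-control set
#'
#' Runs SKAT-O on the positive-control set for each candidate `a2` and
#' returns the value with the smallest p (ties to the smallest `a2`).  The
#' per-candidate table is also returned so the selection is auditable.
#'
#' @param G dosage matrix of the positive-control set (post-filtering).
#' @param null fitted null model.
#' @param grid candidate `a2` values (default 25, 250, 2500).
#' @param a1 fixed first shape parameter (default 1).
#' @param config SKAT-O configuration.
#' @return list with `a2` (selected), `table` (data.frame `a2`, `p`).
#' @export
tune_a2 <- function(G, null, grid = c(25, 250, 2500), a1 = 1,
                    config = skato_config()) {
  if (length(grid) == 0) enh_config_error("empty a2 grid")
  G <- impute_dosages(as.matrix(G))
  if (ncol(G) == 0) enh_data_error("degenerate positive-control set")
  maf <- cohort_maf(G)
  if (any(maf <= 0)) enh_data_error("monomorphic variant in control set")
  p <- vapply(grid, function(a2) {
    skato_p(G, beta_weight(maf, a1, a2), null, config)$p
  }, 0)
  tab <- data.frame(a2 = grid, p = p)
  list(a2 = select_a2(tab), table = tab)
}

#' @rdname tune_a2
#' @param table data.frame with columns `a2` and `p`.
#' @export
select_a2 <- function(table) {
  stopifnot(all(c("a2", "p") %in% names(table)), nrow(table) >= 1)
  best <- table$a2[table$p == min(table$p)]
  min(best)
}
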