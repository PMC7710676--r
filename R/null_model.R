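# Logistic null model: case status ~ intercept + sex + 10 PC eigenvectors.
# All set-based score tests condition on this fit; the residual covariance
# kernel is V - V X (X' V X)^-1 X' V with V = diag(mu (1 - mu)).

#' Fit the covariate-adjusted logistic null model
#'
#' Maximum-likelihood logistic regression of case status on an intercept plus
#' the requested covariates (by convention sex and the first ten principal
#' component eigenvectors of common-variant genotypes).  Constant or aliased
#' covariate columns are dropped with a warning; perfect separation on the
#' covariates is an error (use Firth regression or remove the covariate).
#'
#' @param samples sample table with `status` (1 = case / 0 = control) and
#'   covariate columns.
#' @param covariates character vector of covariate column names (default
#'   `c("sex", "pc1", ..., "pc10")`; use `character()` for intercept-only).
#' @return object of class `enh_null` with the design matrix `X`, fitted
#'   probabilities `mu`, residuals `res = y - mu`, variance weights `v`,
#'   coefficients `alpha_hat`, and the projection factor `XVX_inv`.
#' @export
fit_null <- function(samples, covariates = c("sex", paste0("pc", 1:10))) {
  y <- samples$status
  if (length(unique(y)) < 2)
    enh_data_error("both cases and controls are required")
  missing_cov <- setdiff(covariates, names(samples))
  if (length(missing_cov))
    enh_config_error(paste("covariates not in sample table:",
                           paste(missing_cov, collapse = ", ")))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(samples[, covariates, drop = FALSE]))
  const <- apply(X[, -1, drop = FALSE], 2, function(z) length(unique(z)) == 1)
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(const)[const], collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[-seq_len(qrX$rank)]
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping aliased covariate(s): ",
            paste(setdiff(colnames(X), colnames(X)[keep]), collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  fit <- glm.fit(X, y, family = binomial(),
                 control = list(epsilon = 1e-12, maxit = 100))
  mu <- fit$fitted.values
  eps <- 1e-10
  if (any(mu < eps | mu > 1 - eps))
    enh_data_error(paste("perfect separation on covariates (fitted",
                         "probabilities at 0/1); use Firth regression or",
                         "drop the offending covariate"))
  if (!fit$converged) enh_data_error("null model did not converge")
  v <- mu * (1 - mu)
  XV <- X * v
  structure(list(X = X, y = y, mu = mu, res = y - mu, v = v,
                 alpha_hat = fit$coefficients,
                 XVX_inv = solve(crossprod(X, XV))),
            class = "enh_null")
}

#' @export
print.enh_null <- function(x, ...) {
  cat(sprintf("logistic null model: n = %d (%d cases), %d covariate column(s)\n",
              length(x$y), sum(x$y), ncol(x$X) - 1))
  print(round(x$alpha_hat, 4))
  invisible(x)
}

# M' P M for a n x m matrix M, with P = V - VX (X'VX)^-1 X'V
project_kernel <- function(null, M) {
  VM <- M * null$v
  A <- crossprod(M, VM)
  B <- crossprod(null$X, VM)          # (k x m) = X' V M
  A - crossprod(B, null$XVX_inv %*% B)
}
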