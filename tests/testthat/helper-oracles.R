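# Independent oracles.  Each one recomputes a quantity by a different route
# than the implementation under test (enumeration, brute force, Monte Carlo,
# direct numerical optimization).

# Hardy-Weinberg exact test by the het-count recurrence (the implementation
# uses direct log-factorial evaluation; this oracle builds the distribution
# through the ratio of successive heterozygote configurations instead).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  if (n_AA < n_aa) { tmp <- n_AA; n_AA <- n_aa; n_aa <- tmp }
  N <- n_AA + n_Aa + n_aa
  n <- n_Aa + 2 * n_aa
  hs <- seq(n %% 2, min(n, 2 * N - n), by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1)) {
      h <- hs[i]
      # P(h+2)/P(h) = 4 * hom_minor(h) * hom_major(h) / ((h+1)(h+2))
      hom_min <- (n - h) / 2
      hom_maj <- N - h - hom_min
      probs[i + 1] <- probs[i] * 4 * hom_min * hom_maj / ((h + 1) * (h + 2))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# interval union by point enumeration (coordinates kept small)
oracle_union_bp <- function(start0, end0, limit = 10000) {
  covered <- logical(limit)
  for (i in seq_along(start0))
    covered[(start0[i] + 1):end0[i]] <- TRUE
  sum(covered)
}

# SKAT statistic by the explicit dense formula Q = r' (GW)(GW)' r
oracle_skat_q <- function(G, w, r) {
  K <- (G %*% diag(w, length(w))) %*% t(G %*% diag(w, length(w)))
  drop(t(r) %*% K %*% r)
}

# Monte-Carlo survival of sum lambda_i chisq_1
oracle_quadform_mc <- function(lambda, q, n_draws = 1e6, seed = 99) {
  set.seed(seed)
  tot <- numeric(n_draws)
  for (l in lambda) tot <- tot + l * rchisq(n_draws, 1)
  k <- sum(tot > q)
  p <- k / n_draws
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# Firth penalized log-likelihood maximized directly with optim
oracle_firth_beta <- function(x, y) {
  X <- cbind(1, x)
  negpl <- function(b) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    info <- crossprod(X, X * (mu * (1 - mu)))
    -(sum(y * eta - log1p(exp(eta))) +
        0.5 * determinant(info, logarithm = TRUE)$modulus)
  }
  optim(c(0, 0), negpl, method = "BFGS",
        control = list(reltol = 1e-14, maxit = 1000))$par[2]
}

# exhaustive two-strand PSSM scan written independently (nested loops)
oracle_pssm_best <- function(seq, W, background) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_at <- function(chars, o) {
    s <- 0
    for (i in seq_len(nrow(W))) {
      ch <- chars[o + i - 1]
      s <- s + if (ch == "N") sum(W[i, ] * background) else
        W[i, match(ch, c("A", "C", "G", "T"))]
    }
    s
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  rc <- rev(unname(comp[chars]))
  best <- -Inf
  for (o in seq_len(length(chars) - nrow(W) + 1)) {
    best <- max(best, score_at(chars, o), score_at(rc, o))
  }
  best
}
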