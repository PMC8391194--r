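# Independent oracles used across the suite. These deliberately avoid the
# package's sampler / evidence code paths: the p = 0 posterior is computed
# by exact conjugate algebra given the noise variance combined with dense
# 1-D quadrature over the variance, and R-hat by the textbook
# between/within formula written out directly.

# log N(y; 0, s2*I + v0*X X') -- the exact marginal likelihood over the
# coefficients for a fixed noise variance
log_ml_given_s2 <- function(y, X, s2, v0 = 100) {
  S <- diag(s2, length(y)) + v0 * tcrossprod(X)
  ch <- chol(S)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
}

log_ig <- function(s2, a = 0.01, b = 0.01) {
  a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2
}

# Exact posterior moments and evidence for the p = 0 model:
# conjugate normal algebra for the coefficients given s2, dense grid over s2.
oracle_p0 <- function(y, X, v0 = 100, a = 0.01, b = 0.01,
                      n_grid = 4000, spread = 12) {
  X <- as.matrix(X)
  k <- ncol(X)
  # centre the grid on the residual variance scale
  s2_hat <- sum(stats::lm.fit(X, y)$residuals^2) / length(y)
  grid <- exp(seq(log(s2_hat / spread), log(s2_hat * spread),
                  length.out = n_grid))
  logw <- vapply(grid, function(s2) {
    log_ml_given_s2(y, X, s2, v0) + log_ig(s2, a, b) + log(s2)
  }, numeric(1))  # + log(s2): trapezoid in log-space, du = ds2/s2
  lse <- max(logw) + log(sum(exp(logw - max(logw))))
  d_log <- diff(log(grid))[1]
  log_evidence <- lse + log(d_log)
  w <- exp(logw - lse)
  w <- w / sum(w)
  means <- matrix(0, n_grid, k)
  second <- matrix(0, k, k)
  for (i in seq_len(n_grid)) {
    V <- solve(crossprod(X) / grid[i] + diag(1 / v0, k))
    m <- V %*% crossprod(X, y) / grid[i]
    means[i, ] <- m
    second <- second + w[i] * (V + tcrossprod(m))
  }
  post_mean <- colSums(w * means)
  post_cov <- second - tcrossprod(post_mean)
  list(mean = post_mean,
       sd = sqrt(diag(post_cov)),
       s2_mean = sum(w * grid),
       s2_sd = sqrt(sum(w * grid^2) - sum(w * grid)^2),
       log_evidence = log_evidence)
}

# textbook split-chain potential scale reduction factor
rhat_hand <- function(chains) {
  n <- nrow(chains)
  half <- n %/% 2
  x <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j) {
    cbind(chains[seq_len(half), j], chains[half + seq_len(half), j])
  }))
  W <- mean(apply(x, 2, var))
  B <- half * var(colMeans(x))
  sqrt(((half - 1) / half * W + B / half) / W)
}

# small, fast MCMC settings for unit tests
quick_mcmc <- function(seed = 1, iterations = 1500, burn_in = 500,
                       n_chains = 2) {
  mcmc_config(iterations, burn_in, n_chains, seed)
}

# a small ARX(1) employment-style panel compatible with the diffuse priors.
# the pandemic window is long (half the series) and the infection path
# oscillates within it, so the infection coefficient is identified
# separately from the regime dummy
quick_panel <- function(seed = 1, n = 300) {
  onset <- round(n / 2)
  len <- n - onset + 1
  gen_employment_panel(
    n_weeks = n, alpha0 = 2, alpha1 = -5, alpha2 = -1, phi = 0.5,
    sigma = 0.1, recession_weeks = 40:80, onset_week = onset,
    infection_path = 0.07 + 0.05 * sin(2 * pi * seq_len(len) / 25),
    seed = seed)
}
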