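# Marginal likelihood and posterior model probabilities over AR order.
#
# The evidence is approximated by the Laplace-Metropolis estimator: the
# posterior mean and covariance of the retained draws (with the variance on
# the log scale) stand in for the mode and curvature of the Laplace
# approximation,
#   log m(y) ~= (d/2) log(2*pi) + (1/2) log|S| + log L(theta*) + log pi(theta*),
# evaluated at the posterior mean theta*. The estimator is deterministic
# given the draws and robust at this dimensionality (<= 10 parameters).

# conditional Gaussian log-likelihood of an ARX parameter point
arx_loglik <- function(fit, beta, phi, s2) {
  idx <- fit$data_index
  y <- fit$y
  yt <- y[idx]
  spec <- fit$spec
  mu <- rep(beta[1L], length(idx))
  if (length(spec$exog_names)) {
    mu <- mu + drop(fit$exog[idx, spec$exog_names, drop = FALSE] %*%
                      beta[-1L])
  }
  if (spec$p > 0L) {
    for (i in seq_len(spec$p)) mu <- mu + phi[i] * y[idx - i]
  }
  sum(dnorm(yt, mu, sqrt(s2), log = TRUE))
}

#' Log marginal likelihood of an ARX model (Laplace-Metropolis)
#'
#' @param y Outcome series.
#' @param exog Covariate matrix or \code{NULL}.
#' @param spec An \code{\link{arx_spec}}.
#' @param mcmc An \code{\link{mcmc_config}}.
#' @param condition_on Initial observations excluded from the likelihood
#'   (default the lag order); pass a common value when comparing models.
#' @param fit Optionally a pre-computed \code{\link{arx_fit}} on the same
#'   data and window, to avoid refitting.
#' @return The log evidence estimate (finite scalar), with the underlying
#'   fit attached as attribute \code{"fit"}.
#' @export
log_marginal_likelihood <- function(y, exog = NULL, spec, mcmc = mcmc_config(),
                                    condition_on = NULL, fit = NULL) {
  if (is.null(fit)) {
    fit <- suppressWarnings(fit_arx(y, exog, spec, mcmc, condition_on))
  }
  pd <- pooled_draws(fit)
  kb <- 1L + length(spec$exog_names)
  p <- spec$p
  theta <- cbind(pd[, seq_len(kb + p), drop = FALSE],
                 log_sigma2 = log(pd[, "sigma2"]))
  tbar <- colMeans(theta)
  S <- cov(theta)
  d <- ncol(theta)
  ldetS <- determinant(S, logarithm = TRUE)$modulus
  beta <- tbar[seq_len(kb)]
  phi <- if (p > 0L) tbar[kb + seq_len(p)] else numeric()
  s2 <- exp(tbar[d])
  ll <- arx_loglik(fit, beta, phi, s2)
  lo <- spec$ar_bounds[1L]
  hi <- spec$ar_bounds[2L]
  lprior <- sum(dnorm(beta, 0, sqrt(spec$coef_var), log = TRUE))
  if (p > 0L) {
    if (any(phi < lo | phi > hi)) return(-Inf)
    lprior <- lprior + p * log(1 / (hi - lo))
  }
  # inverse-gamma prior on sigma2, plus Jacobian for the log-scale parameter
  a0 <- spec$var_shape
  b0 <- spec$var_rate
  lprior <- lprior + a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(s2) - b0 / s2 +
    log(s2)
  lev <- d / 2 * log(2 * pi) + 0.5 * as.numeric(ldetS) + ll + lprior
  attr(lev, "fit") <- fit
  lev
}

#' Posterior model probabilities over AR order
#'
#' Scores ARX models with lag orders 1 through \code{p_max} on the common
#' observation window (the first \code{p_max} observations are excluded from
#' every candidate's likelihood so all candidates see identical data), and
#' converts log evidences into posterior model probabilities under a uniform
#' prior over candidates.
#'
#' @param y Outcome series.
#' @param exog Covariate matrix shared by all candidates, or \code{NULL}.
#' @param p_max Largest candidate order (default 7).
#' @param mcmc An \code{\link{mcmc_config}}; the same seed is used for every
#'   candidate, so the comparison is deterministic.
#' @param exog_names Covariate names (defaults to \code{colnames(exog)}).
#' @return A \code{data.frame} of class \code{lag_comparison} with columns
#'   \code{lag}, \code{log_evidence}, \code{posterior_prob}; the modal order
#'   is attached as attribute \code{"best"}.
#' @export
select_lag <- function(y, exog = NULL, p_max = 7L, mcmc = mcmc_config(),
                       exog_names = colnames(exog)) {
  p_max <- as.integer(p_max)
  if (is.na(p_max) || p_max < 1L) stop_input("`p_max` must be at least 1")
  if (length(y) < p_max + 10L)
    stop_input("series too short for the largest candidate order")
  lags <- seq_len(p_max)
  lev <- vapply(lags, function(p) {
    spec <- arx_spec(p, exog_names = exog_names %||% character())
    as.numeric(log_marginal_likelihood(y, exog, spec, mcmc,
                                       condition_on = p_max))
  }, numeric(1L))
  prob <- exp(lev - max(lev))
  prob <- prob / sum(prob)
  out <- data.frame(lag = lags, log_evidence = lev, posterior_prob = prob)
  attr(out, "best") <- lags[which.max(prob)]
  class(out) <- c("lag_comparison", "data.frame")
  out
}

#' @export
print.lag_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$posterior_prob <- round(df$posterior_prob, 4)
  print.data.frame(df, row.names = FALSE)
  cat("modal lag order:", attr(x, "best"), "\n")
  invisible(x)
}

#' Write a lag-comparison table to CSV
#'
#' Columns \code{lag,log_evidence,posterior_prob} (probabilities to 4
#' decimal places).
#' @param comparison A \code{\link{select_lag}} result.
#' @param path Output path.
#' @export
write_comparison_csv <- function(comparison, path) {
  df <- as.data.frame(comparison)
  df$posterior_prob <- round(df$posterior_prob, 4)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
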