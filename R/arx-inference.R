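# Posterior summaries, convergence diagnostics, one-step-ahead prediction
# and out-of-sample evaluation for arx_fit objects.

#' Posterior summary with HPD intervals
#'
#' Mean, standard deviation, and highest-posterior-density interval per
#' parameter over the pooled retained draws. The HPD is the shortest
#' contiguous interval containing \code{cred} of the draws.
#'
#' @param fit An \code{\link{arx_fit}}.
#' @param cred Credible mass in (0, 1]; default 0.95.
#' @return A \code{data.frame} with columns \code{parameter}, \code{mean},
#'   \code{sd}, \code{hpd_lower}, \code{hpd_upper}.
#' @export
posterior_summary <- function(fit, cred = 0.95) {
  stopifnot(inherits(fit, "arx_fit"))
  pd <- pooled_draws(fit)
  if (nrow(pd) < 100L)
    stop_input("need at least 100 retained draws for a summary")
  hpd <- apply(pd, 2L, hpd_interval, cred = cred)
  out <- data.frame(parameter = colnames(pd),
                    mean = colMeans(pd),
                    sd = apply(pd, 2L, sd),
                    hpd_lower = hpd[1L, ],
                    hpd_upper = hpd[2L, ],
                    row.names = NULL)
  attr(out, "cred") <- cred
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Write a posterior summary table to CSV
#'
#' Columns \code{parameter,mean,sd,hpd_lower,hpd_upper}.
#' @param summary A \code{\link{posterior_summary}}.
#' @param path Output path.
#' @export
write_summary_csv <- function(summary, path) {
  write.csv(as.data.frame(summary), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# split each chain in half so within-chain drift shows up as between-chain
# disagreement
split_chain_matrix <- function(x) {
  n <- nrow(x)
  half <- n %/% 2L
  x <- x[seq_len(2L * half), , drop = FALSE]
  do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[half + seq_len(half), j])
  }))
}

#' Convergence diagnostics: split R-hat and bulk effective sample size
#'
#' Split-chain potential scale reduction factor and an effective sample size
#' based on the combined-chain autocorrelation sequence with Geyer's initial
#' positive/monotone truncation. R-hat at or below 1.05 is treated as
#' passing elsewhere in the package.
#'
#' @param fit An \code{\link{arx_fit}} with at least two chains.
#' @return A list with named numeric vectors \code{rhat} and \code{ess}.
#' @export
convergence_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "arx_fit"))
  d <- fit$draws
  if (dim(d)[2L] < 2L)
    stop_input("diagnostics need at least 2 chains; ",
               "re-run with n_chains >= 2 (split-chain mode)")
  pars <- dimnames(d)[[3L]]
  rhat <- ess <- setNames(rep(NA_real_, length(pars)), pars)
  for (j in seq_along(pars)) {
    x <- split_chain_matrix(d[, , j, drop = TRUE])
    nn <- nrow(x)
    m <- ncol(x)
    w <- mean(apply(x, 2L, var))
    b <- nn * var(colMeans(x))
    if (w <= .Machine$double.eps * max(1, abs(mean(x)))^2 || !is.finite(w)) {
      warning("parameter ", pars[j],
              " has (near-)constant chains; diagnostics degenerate",
              call. = FALSE)
      next
    }
    var_plus <- (nn - 1) / nn * w + b / nn
    rhat[j] <- sqrt(var_plus / w)
    # combined autocorrelation (Vehtari et al. construction)
    max_lag <- nn - 1L
    acov <- vapply(seq_len(m), function(cc) {
      drop(acf(x[, cc], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf)
    }, numeric(max_lag + 1L))
    rho <- 1 - (w - rowMeans(acov)) / var_plus
    rho[1L] <- 1
    # Geyer: sum consecutive pairs while positive, enforce monotone decay
    n_pairs <- (length(rho)) %/% 2L
    pk <- rho[2L * seq_len(n_pairs) - 1L] + rho[2L * seq_len(n_pairs)]
    keep <- which(pk <= 0)
    if (length(keep)) pk <- pk[seq_len(keep[1L] - 1L)]
    if (length(pk) > 1L) pk <- cummin(pk)
    tau <- max(-1 + 2 * sum(pk), 1 / (m * nn))
    ess[j] <- min(m * nn / tau, m * nn)
  }
  list(rhat = rhat, ess = ess)
}

#' One-step-ahead posterior predictive draws
#'
#' For each retained posterior draw, forms the linear predictor from the
#' supplied lagged outcome values and scenario covariates and adds one
#' normal noise draw with that draw's variance.
#'
#' @param fit An \code{\link{arx_fit}}.
#' @param last_lags The most recent \code{p} outcome values, ordered most
#'   recent first (\code{last_lags[1]} is \eqn{y_{t}}, feeding lag 1).
#' @param exog_scenario Named values for every covariate in the spec (e.g.,
#'   \code{c(infection_rate = 0.15, dummy = 1)}); \code{NULL} when the spec
#'   has none.
#' @param seed Integer seed for the noise draws.
#' @return An object of class \code{predictive_draws}: a numeric vector of
#'   draws with the scenario recorded as attributes.
#' @export
predict_next <- function(fit, last_lags = numeric(), exog_scenario = NULL,
                         seed = 1L) {
  stopifnot(inherits(fit, "arx_fit"))
  spec <- fit$spec
  if (length(last_lags) != spec$p)
    stop_input("`last_lags` must supply exactly p = ", spec$p, " values")
  if (length(spec$exog_names)) {
    if (is.null(exog_scenario) ||
        !all(spec$exog_names %in% names(exog_scenario)))
      stop_input("`exog_scenario` must name every covariate: ",
                 paste(spec$exog_names, collapse = ", "))
    exog_scenario <- exog_scenario[spec$exog_names]
  }
  pd <- pooled_draws(fit)
  mu <- pd[, "intercept"]
  for (nm in spec$exog_names) mu <- mu + pd[, nm] * exog_scenario[[nm]]
  if (spec$p > 0L) {
    for (i in seq_len(spec$p)) {
      mu <- mu + pd[, paste0("ar", i)] * last_lags[i]
    }
  }
  set.seed(as.integer(seed))
  draws <- mu + rnorm(nrow(pd), 0, sqrt(pd[, "sigma2"]))
  structure(draws, class = "predictive_draws",
            last_lags = last_lags, exog_scenario = exog_scenario)
}

#' One-week-ahead out-of-sample RMSE
#'
#' Expanding-window evaluation: for each holdout step the model is refit on
#' all earlier observations, the one-step-ahead predictive mean is formed,
#' and the root-mean-square error against the realized values is reported on
#' the outcome's native scale and as a percentage of the holdout mean.
#'
#' @param y Outcome series.
#' @param exog Covariate matrix aligned to \code{y}, or \code{NULL}.
#' @param spec An \code{\link{arx_spec}}.
#' @param mcmc An \code{\link{mcmc_config}}; each refit derives its seed
#'   from it so the evaluation is deterministic.
#' @param holdout_steps Number of terminal observations held out.
#' @return A list: \code{rmse}, \code{rmse_pct} (percent of the holdout
#'   mean), \code{predicted}, \code{actual}.
#' @export
one_step_oos_rmse <- function(y, exog = NULL, spec, mcmc = mcmc_config(),
                              holdout_steps = 1L) {
  holdout_steps <- as.integer(holdout_steps)
  n <- length(y)
  if (holdout_steps < 1L) stop_input("`holdout_steps` must be at least 1")
  if (holdout_steps >= n) stop_input("holdout longer than the series")
  if (n - holdout_steps < spec$p + 10L)
    stop_input("training window too short for the lag order")
  preds <- numeric(holdout_steps)
  for (h in seq_len(holdout_steps)) {
    t_pred <- n - holdout_steps + h
    train <- seq_len(t_pred - 1L)
    cfg <- mcmc_config(mcmc$iterations, mcmc$burn_in, mcmc$n_chains,
                       mcmc$seed + h)
    fit <- suppressWarnings(
      fit_arx(y[train], if (!is.null(exog)) exog[train, , drop = FALSE],
              spec, cfg))
    lags <- if (spec$p > 0L) y[(t_pred - 1L):(t_pred - spec$p)] else numeric()
    scen <- if (length(spec$exog_names)) {
      setNames(as.numeric(exog[t_pred, spec$exog_names]), spec$exog_names)
    }
    pdraw <- predict_next(fit, lags, scen, seed = cfg$seed)
    preds[h] <- mean(pdraw)
  }
  actual <- y[(n - holdout_steps + 1L):n]
  rmse <- sqrt(mean((preds - actual)^2))
  list(rmse = rmse,
       rmse_pct = 100 * rmse / mean(abs(actual)),
       predicted = preds, actual = actual)
}
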