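# the sampler and its inference layer, checked against independent oracles
# and degenerate constructions

fake_fit <- function(draws_list, p = 0, exog_names = character()) {
  # build an arx_fit by hand so degenerate posteriors can be injected
  n_keep <- length(draws_list[[1]]) / 2
  arr <- array(NA_real_, dim = c(n_keep, 2, length(draws_list)),
               dimnames = list(NULL, NULL, names(draws_list)))
  for (j in seq_along(draws_list)) arr[, , j] <- draws_list[[j]]
  structure(list(draws = arr,
                 spec = arx_spec(p, exog_names = exog_names),
                 mcmc = mcmc_config(2 * n_keep, n_keep, 2, 1),
                 warnings = character()),
            class = "arx_fit")
}

test_that("input contracts are enforced", {
  spec <- arx_spec(2)
  expect_error(fit_arx(rnorm(5), spec = spec, mcmc = quick_mcmc()),
               "insufficient data")
  expect_error(fit_arx(c(rnorm(50), NA), spec = spec, mcmc = quick_mcmc()),
               "non-finite")
  expect_error(arx_spec(-1), "non-negative")
  expect_error(mcmc_config(100, 200), "burn_in")
})

test_that("p = 0 posterior moments match the conjugate/quadrature oracle", {
  set.seed(42)
  n <- 60
  X <- cbind(1, x1 = rnorm(n), x2 = runif(n))
  beta_true <- c(1, -2, 0.5)
  y <- drop(X %*% beta_true) + rnorm(n, 0, 0.5)
  spec <- arx_spec(0, exog_names = c("x1", "x2"))
  fit <- fit_arx(y, X[, 2:3], spec, mcmc_config(6000, 1000, 2, 9))
  s <- posterior_summary(fit)
  ora <- oracle_p0(y, X)
  ess <- convergence_diagnostics(fit)$ess
  for (j in 1:3) {
    mcse <- s$sd[j] / sqrt(ess[j])
    expect_lt(abs(s$mean[j] - ora$mean[j]), 3 * mcse + 1e-8)
    expect_lt(abs(s$sd[j] - ora$sd[j]) / ora$sd[j], 0.1)
  }
  expect_lt(abs(s$mean[4] - ora$s2_mean),
            3 * s$sd[4] / sqrt(ess["sigma2"]) + 0.02 * ora$s2_mean)
})

test_that("ARX(1) recovery: true parameters inside their 95% HPDs", {
  panel <- quick_panel(seed = 3, n = 500)
  truth <- attr(panel, "truth")
  spec <- arx_spec(1, exog_names = c("infection_rate", "dummy"))
  fit <- fit_arx(panel$employment_pct,
                 as.matrix(panel[, c("infection_rate", "dummy")]),
                 spec, mcmc_config(4000, 1000, 2, 5))
  s <- posterior_summary(fit)
  expected <- c(intercept = truth$alpha0, infection_rate = truth$alpha1,
                dummy = truth$alpha2, ar1 = truth$phi, sigma2 = truth$sigma^2)
  for (nm in names(expected)) {
    row <- s[s$parameter == nm, ]
    expect_gt(expected[[nm]], row$hpd_lower)
    expect_lt(expected[[nm]], row$hpd_upper)
  }
})

test_that("draws respect the prior support and the seed", {
  panel <- quick_panel(seed = 11)
  spec <- arx_spec(2, exog_names = "infection_rate")
  X <- as.matrix(panel[, "infection_rate", drop = FALSE])
  f1 <- suppressWarnings(fit_arx(panel$employment_pct, X, spec, quick_mcmc(4)))
  f2 <- suppressWarnings(fit_arx(panel$employment_pct, X, spec, quick_mcmc(4)))
  expect_identical(f1$draws, f2$draws)
  pd <- pooled_draws <- matrix(f1$draws, ncol = dim(f1$draws)[3],
                               dimnames = list(NULL, dimnames(f1$draws)[[3]]))
  expect_true(all(pd[, "ar1"] >= -1 & pd[, "ar1"] <= 1))
  expect_true(all(pd[, "ar2"] >= -1 & pd[, "ar2"] <= 1))
  expect_true(all(pd[, "sigma2"] > 0))
})

test_that("posterior_summary handles degenerate and known distributions", {
  f <- fake_fit(list(theta = rep(5, 400), sigma2 = rep(1, 400)))
  s <- posterior_summary(f)
  expect_equal(s$mean[1], 5)
  expect_equal(s$sd[1], 0)
  expect_equal(c(s$hpd_lower[1], s$hpd_upper[1]), c(5, 5))

  # deterministic standard-normal quantile grid: no Monte-Carlo noise
  g <- qnorm(ppoints(1e5))
  hg <- hpd_interval(g, 0.95)
  expect_lt(abs(hg[["lower"]] + 1.96), 0.01)
  expect_lt(abs(hg[["upper"]] - 1.96), 0.01)

  # random draws: the shortest-window endpoints converge slowly (cube-root
  # rate), so the tolerance reflects the estimator noise at this n
  set.seed(8)
  z <- rnorm(1e6)
  h <- hpd_interval(z, 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.04)
  expect_lt(abs(h[["upper"]] - 1.96), 0.04)
  expect_gte(mean(z >= h[["lower"]] & z <= h[["upper"]]), 0.95 - 2e-6)
  expect_equal(unname(hpd_interval(z, 1)), range(z))
  expect_error(posterior_summary(f, cred = 1.5), "cred")
})

test_that("split R-hat matches the hand formula and flags separated chains", {
  set.seed(21)
  good <- cbind(rnorm(1000), rnorm(1000))
  bad <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  f <- fake_fit(list(good = as.vector(good), bad = as.vector(bad),
                     sigma2 = abs(rnorm(2000)) + 1))
  d <- convergence_diagnostics(f)
  expect_lt(abs(d$rhat[["good"]] - rhat_hand(good)), 1e-10)
  expect_lt(abs(d$rhat[["bad"]] - rhat_hand(bad)), 1e-10)
  expect_lt(abs(d$rhat[["good"]] - 1), 0.01)
  expect_gt(d$rhat[["bad"]], 3)
  expect_true(all(d$ess <= 2000, na.rm = TRUE))

  const <- fake_fit(list(theta = rep(2, 800), sigma2 = abs(rnorm(800)) + 1))
  expect_warning(convergence_diagnostics(const), "constant")

  one_chain <- fake_fit(list(theta = rnorm(400), sigma2 = rep(1, 400)))
  one_chain$draws <- one_chain$draws[, 1, , drop = FALSE]
  expect_error(convergence_diagnostics(one_chain), "2 chains")
})

test_that("predict_next is the linear predictor plus posterior noise", {
  # degenerate posterior with zero variance: prediction is exact
  f <- fake_fit(list(intercept = rep(2, 400), x = rep(-3, 400),
                     ar1 = rep(0.5, 400), sigma2 = rep(0, 400)),
                p = 1, exog_names = "x")
  pr <- predict_next(f, last_lags = 10, exog_scenario = c(x = 0.2), seed = 1)
  expect_equal(unique(as.numeric(pr)), 2 - 3 * 0.2 + 0.5 * 10)

  expect_error(predict_next(f, last_lags = numeric(),
                            exog_scenario = c(x = 0.2)), "exactly p")
  expect_error(predict_next(f, last_lags = 10), "exog_scenario")

  # law of iterated expectations on a real fit
  panel <- quick_panel(seed = 5)
  spec <- arx_spec(1, exog_names = c("infection_rate", "dummy"))
  fit <- fit_arx(panel$employment_pct,
                 as.matrix(panel[, c("infection_rate", "dummy")]),
                 spec, quick_mcmc(2))
  s <- posterior_summary(fit)
  lag1 <- tail(panel$employment_pct, 1)
  scen <- c(infection_rate = 0.15, dummy = 1)
  pr <- predict_next(fit, lag1, scen, seed = 9)
  m <- setNames(s$mean, s$parameter)
  lin <- m["intercept"] + m["infection_rate"] * 0.15 + m["dummy"] +
    m["ar1"] * lag1
  expect_lt(abs(mean(pr) - lin), 4 * sd(pr) / sqrt(length(pr)))
})

test_that("draws serialize to long-format CSV", {
  f <- fake_fit(list(intercept = rnorm(100), sigma2 = abs(rnorm(100)) + 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(f, path)
  long <- read.csv(path)
  expect_equal(names(long), c("chain", "iteration", "parameter", "value"))
  expect_equal(nrow(long), 100 * 2)
  expect_equal(sort(unique(long$parameter)), c("intercept", "sigma2"))
  expect_equal(long$value[long$parameter == "intercept" & long$chain == 1],
               f$draws[, 1, "intercept"])
})

test_that("one-step out-of-sample evaluation validates its window", {
  y <- as.numeric(quick_panel(seed = 6)$employment_pct)
  spec <- arx_spec(1)
  expect_error(one_step_oos_rmse(y, spec = spec, holdout_steps = 400),
               "holdout")
  res <- one_step_oos_rmse(y, spec = spec, mcmc = quick_mcmc(3),
                           holdout_steps = 3)
  expect_gte(res$rmse, 0)
  expect_equal(res$rmse_pct, 100 * res$rmse / mean(abs(res$actual)))
  expect_length(res$predicted, 3)
})
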