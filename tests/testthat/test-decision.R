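# the net-benefit decision rule and the scenario look-up machinery

fl <- fixture_florida_tables()
fl_un <- fl$delta_nb[fl$delta_nb$income == "unadjusted", ]

test_that("delta_nb handles degenerate and analytic reference cases", {
  d0 <- delta_nb(c(mean = 100, sd = 0), c(mean = 40, sd = 0), n_draws = 50)
  expect_equal(d0$mean, 60)
  expect_equal(d0$sd, 0)
  expect_equal(d0$p_positive, 1)

  dneg <- delta_nb(c(mean = 10, sd = 0), c(mean = 40, sd = 0), n_draws = 50)
  expect_equal(dneg$p_positive, 0)

  # P(> 0) for a normal(9404, 28086^2) difference: Phi(mu/sigma) = 0.6311
  big <- delta_nb(c(mean = 9404, sd = 28086), c(mean = 0, sd = 0),
                  n_draws = 2e5, seed = 3)
  expect_equal(big$p_positive, pnorm(9404 / 28086), tolerance = 0.01)
  expect_equal(pnorm(9404 / 28086), 0.6311, tolerance = 1e-4)

  expect_error(delta_nb(c(mean = 1, sd = 1), c(mean = 1, sd = 1),
                        n_draws = 1), "at least 2")
})

test_that("delta_nb accepts draw vectors and records provenance", {
  set.seed(6)
  b <- income_from_employment(rnorm(5000, 96, 1), 52426)
  co <- total_cost(rnorm(5000, 0.04, 0.01), 0.15)
  d <- delta_nb(b, co, n_draws = 5000, seed = 2, scenario_rate = 0.15,
                income_label = "unadjusted")
  expect_equal(d$mean, mean(b) - mean(co), tolerance = 0.05)
  expect_equal(d$scenario_rate, 0.15)
  expect_lt(d$q2.5, d$q97.5)
})

test_that("decide is the conjunction of the mean and threshold conditions", {
  expect_equal(decide(list(mean = 42964, p_positive = 0.9998), T = 0.9),
               "reopen")
  expect_equal(decide(list(mean = 100, p_positive = 0.5), T = 0.9),
               "do_not_reopen")
  expect_equal(decide(list(mean = -5, p_positive = 0.99), T = 0.9),
               "do_not_reopen")
  expect_error(decide(list(mean = 1, p_positive = 1), T = 0), "0, 1")
  expect_error(decide(list(mean = 1, p_positive = 1), T = 1.2), "0, 1")

  # monotone: raising p_positive never flips reopen -> do_not_reopen
  for (p in seq(0, 1, by = 0.05)) {
    lower <- decide(list(mean = 10, p_positive = p), T = 0.6)
    upper <- decide(list(mean = 10, p_positive = min(p + 0.2, 1)), T = 0.6)
    expect_false(lower == "reopen" && upper == "do_not_reopen")
  }
})

test_that("expected infection rate is the probability-weighted grid value", {
  expect_equal(expected_infection_rate(c(0.5, 0.3, 0.1, 0.1)), 14)
  expect_equal(expected_infection_rate(c(0.0, 0.1, 0.4, 0.5)), 22)
  expect_equal(expected_infection_rate(rep(0.25, 4)), 17.5)
  expect_error(expected_infection_rate(c(0.5, 0.3, 0.1, 0.2)), "sum to 1")
})

test_that("expected policy benefit is the weighted mean of per-rate means", {
  means <- fl_un$mean
  expect_equal(scenario_expected_benefit(means, c(0.5, 0.3, 0.1, 0.1)), 29754)
  expect_equal(scenario_expected_benefit(means, c(0.0, 0.1, 0.4, 0.5)), 2209)
  expect_equal(scenario_expected_benefit(means, c(1, 0, 0, 0)), 42964)

  named <- setNames(means[1:3], c("10", "15", "20"))
  expect_error(scenario_expected_benefit(named, c(0.1, 0.2, 0.4, 0.3)),
               "missing")
  # a rate with zero weight may be absent
  expect_equal(scenario_expected_benefit(setNames(means, c("10", "15", "20", "25")),
                                         c(0.5, 0.3, 0.1, 0.1)), 29754)
})

test_that("P_j: weighted-sum Monte Carlo agrees with its closed form", {
  means <- fl_un$mean
  sds <- fl_un$sd
  major <- c(0.1, 0.2, 0.4, 0.3)
  analytic <- scenario_prob_positive(means, sds, major, analytic = TRUE)
  sig <- sqrt(sum(major^2 * sds^2))
  expect_equal(analytic, pnorm(sum(major * means) / sig))
  expect_equal(analytic, 0.7495, tolerance = 5e-4)

  mc <- scenario_prob_positive(means, sds, major, n_draws = 1e5, seed = 12)
  expect_equal(mc, analytic, tolerance = 0.005)

  # degenerate: all positive means with zero spread
  expect_equal(scenario_prob_positive(c(1, 2, 3, 4), rep(0, 4),
                                      rep(0.25, 4), n_draws = 100), 1)
  expect_error(scenario_prob_positive(means, sds, c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("mixture mechanism differs from the weighted sum as expected", {
  means <- fl_un$mean
  sds <- fl_un$sd
  minor <- c(0.5, 0.3, 0.1, 0.1)
  mix <- scenario_prob_positive(means, sds, minor, analytic = TRUE,
                                mechanism = "mixture")
  ws <- scenario_prob_positive(means, sds, minor, analytic = TRUE)
  expect_equal(mix, sum(minor * pnorm(means / sds)))
  expect_lt(mix, 0.9)   # the mixture cannot reach the table's 0.9988
  expect_gt(ws, 0.99)
})

test_that("look-up table applies both choice rules and the documented tie-break", {
  tab <- build_lookup_table(
    data.frame(rate = c(10, 15, 20, 25), mean = fl_un$mean, sd = fl_un$sd),
    fl$scenarios["scenario_1"], T = 0.90, analytic = TRUE)
  ch <- attr(tab, "choices")$scenario_1
  expect_equal(ch$risk_neutral, "Minor")
  expect_equal(ch$risk_averse, "Minor")

  # all P_j below the threshold -> risk-averse abstains
  low <- build_lookup_table(
    data.frame(rate = c(10, 15, 20, 25), mean = rep(1, 4),
               sd = rep(1e6, 4)),
    fl$scenarios["scenario_1"], T = 0.99, analytic = TRUE)
  expect_equal(attr(low, "choices")$scenario_1$risk_averse, "none")

  # constructed exact tie in E(B_j): the earlier (less disruptive) policy wins
  tie <- build_lookup_table(
    data.frame(rate = c(10, 15, 20, 25), mean = c(100, 100, 100, 100),
               sd = rep(10, 4)),
    list(s = scenario_matrix(rbind(c(0.4, 0.3, 0.2, 0.1),
                                   c(0.1, 0.2, 0.3, 0.4),
                                   c(0.25, 0.25, 0.25, 0.25)))),
    T = 0.5, analytic = TRUE)
  expect_equal(attr(tie, "choices")$s$risk_neutral, "Minor")

  expect_error(build_lookup_table(fl_un, list(), T = 0.9), "non-empty")
})

test_that("mixture-mean identity: E(B_j) equals the mean weighted-sum draw", {
  means <- fl_un$mean
  sds <- fl_un$sd
  row <- c(0.2, 0.4, 0.2, 0.2)
  set.seed(77)
  draws <- matrix(rnorm(4e5, rep(means, each = 1e5), rep(sds, each = 1e5)),
                  ncol = 4)
  mc_mean <- mean(draws %*% row)
  expect_equal(mc_mean, sum(row * means),
               tolerance = 3 * sqrt(sum(row^2 * sds^2) / 1e5) /
                 abs(sum(row * means)))
})
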