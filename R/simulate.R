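# Seed-deterministic generators for synthetic panels with known ground
# truth, plus the Florida reference tables used by the decision-stage
# golden tests.
#
# The generators realise exactly the statistical structure the two ARX
# models assume: the employment generator runs the weekly ARX recursion
# directly, and the epidemic generator first simulates the daily
# fatality-rate ARX process and then back-constructs cumulative death
# counts so that the rate constructors recover the simulated process to
# within count-rounding error. Default parameter values are the posterior
# means of the fitted Florida models, so the default panels mimic the study
# series (weekly employment 2007 through spring 2020 with the 2008
# recession and 2020 pandemic regime windows; a four-month daily epidemic
# panel with test volumes growing into the millions).

#' Generate a synthetic weekly employment panel
#'
#' Runs the recursion
#' \eqn{E_t = a_0 + a_1 c_t + a_2 d_t + \sum_i \phi_i E_{t-i} + e_t},
#' \eqn{e_t \sim N(0, \sigma^2)}, over a dummy schedule with one recession
#' window and one open-ended pandemic window, and an infection-rate path
#' that is zero before pandemic onset.
#'
#' @param n_weeks Number of weeks (default 695, fourteen years).
#' @param alpha0,alpha1,alpha2 Intercept, infection-rate and regime-dummy
#'   coefficients on the percent-employment scale.
#' @param phi AR coefficients (each within \code{[-1, 1]}).
#' @param sigma Noise SD (> 0).
#' @param recession_weeks Index range coded 1 in the dummy for the recession
#'   regime.
#' @param onset_week First week of the pandemic regime; the dummy is 1 from
#'   here onward and the infection-rate path begins here. Defaults to 30
#'   weeks before the end of the series.
#' @param infection_path Infection-rate fractions from \code{onset_week} to
#'   the end (recycled/truncated as needed); zero before onset.
#' @param init Initial lag values (default: the deterministic steady state
#'   of the pre-pandemic recursion).
#' @param start_date First week-start date (a Monday).
#' @param seed Integer seed.
#' @return A \code{\link{weekly_series}} with the generating parameters
#'   attached as attribute \code{"truth"}.
#' @export
gen_employment_panel <- function(n_weeks = 695L,
                                 alpha0 = 0.6016, alpha1 = -5.6685,
                                 alpha2 = -0.0511,
                                 phi = c(0.3174, 0.9884, -0.0559, -0.2559),
                                 sigma = sqrt(0.0239),
                                 recession_weeks = 53:170,
                                 onset_week = max(1L, n_weeks - 30L),
                                 infection_path = seq(0.01, 0.10,
                                                      length.out = 31L),
                                 init = NULL,
                                 start_date = as.Date("2007-01-01"),
                                 seed = 1L) {
  p <- length(phi)
  if (sigma <= 0) stop_input("`sigma` must be positive")
  if (any(abs(phi) > 1)) stop_input("each AR coefficient must lie in [-1, 1]")
  if (onset_week > n_weeks) stop_input("`onset_week` must fall in the series")
  s <- sum(phi)
  if (abs(s) >= 1)
    warning("AR coefficients sum to ", round(s, 3),
            "; the recursion may drift off the 0-100 scale", call. = FALSE)
  dummy <- numeric(n_weeks)
  dummy[intersect(recession_weeks, seq_len(n_weeks))] <- 1
  dummy[onset_week:n_weeks] <- 1
  c_path <- numeric(n_weeks)
  post <- onset_week:n_weeks
  c_path[post] <- rep_len(infection_path, length(post))
  if (is.null(init)) init <- rep(alpha0 / (1 - min(s, 0.999)), p)
  if (length(init) != p) stop_input("`init` must supply p lag values")
  set.seed(as.integer(seed))
  eps <- rnorm(n_weeks, 0, sigma)
  e <- numeric(n_weeks)
  # init is ordered most recent first (init[1] feeds lag 1 at t = 1)
  hist <- init
  for (t in seq_len(n_weeks)) {
    e[t] <- alpha0 + alpha1 * c_path[t] + alpha2 * dummy[t] +
      (if (p > 0L) sum(phi * hist) else 0) + eps[t]
    if (p > 0L) hist <- c(e[t], hist[-p])
  }
  e <- pmin(pmax(e, 0), 100)
  out <- weekly_series(start_date + 7L * (seq_len(n_weeks) - 1L),
                       e, dummy, c_path)
  attr(out, "truth") <- list(alpha0 = alpha0, alpha1 = alpha1,
                             alpha2 = alpha2, phi = phi, sigma = sigma,
                             init = init, onset_week = onset_week,
                             seed = as.integer(seed))
  out
}

#' Generate a synthetic daily epidemic count panel
#'
#' Simulates the daily fatality-rate process
#' \eqn{w_t = g_0 + g_1 c_t + \sum_i \phi_i w_{t-i} + e_t} (clipped to
#' [0, 1] with a warning if a draw escapes), then back-constructs cumulative
#' counts: \code{cum_positives = round(c * cum_tests)} and
#' \code{cum_deaths[t] = round(w[t] * cum_positives[t - lag])}, both forced
#' non-decreasing. Running \code{\link{compute_death_rate}} on the output
#' recovers the simulated process within count-rounding error.
#'
#' @param n_days Number of days (default 120).
#' @param gamma0,gamma1 Intercept and infection-rate coefficients of the
#'   fatality-rate process.
#' @param phi AR coefficients.
#' @param sigma Noise SD of the rate process. The default 0.001 (about 2%
#'   of the default rate level) keeps the simulated path as smooth as a
#'   ratio of cumulative counts can actually be, so the monotone count
#'   construction below rarely binds; larger values produce rate paths
#'   that cumulative deaths cannot track downward.
#' @param infection_path Daily infection-rate fractions (recycled to
#'   \code{n_days}).
#' @param tests_path Cumulative test counts per day (non-decreasing;
#'   default exponential growth of 4% per day from 2e5, capped at 5e7, so
#'   count rounding is negligible and lagged cases outgrow downward rate
#'   moves).
#' @param lag_days Case-to-death lag (default 7).
#' @param init Initial lag values for the rate process (default: its
#'   deterministic steady state).
#' @param start_date First calendar day.
#' @param seed Integer seed.
#' @return A \code{\link{daily_epidemic_series}} with attribute
#'   \code{"truth"} recording the parameters and the simulated rate path.
#' @export
gen_epidemic_panel <- function(n_days = 120L,
                               gamma0 = 0.0008, gamma1 = 0.0467,
                               phi = c(0.8693, 0.0282),
                               sigma = 0.001,
                               infection_path = 0.08,
                               tests_path = NULL,
                               lag_days = 7L,
                               init = NULL,
                               start_date = as.Date("2020-03-01"),
                               seed = 1L) {
  m <- length(phi)
  if (sigma <= 0) stop_input("`sigma` must be positive")
  c_path <- rep_len(infection_path, n_days)
  if (is.null(tests_path)) {
    tests_path <- round(pmin(2e5 * exp(0.04 * (seq_len(n_days) - 1)), 5e7))
  }
  if (length(tests_path) != n_days || any(diff(tests_path) < 0))
    stop_input("`tests_path` must be non-decreasing with one value per day")
  s <- sum(phi)
  if (is.null(init)) {
    init <- rep((gamma0 + gamma1 * mean(c_path)) / (1 - min(s, 0.999)), m)
  }
  if (length(init) != m) stop_input("`init` must supply m lag values")
  set.seed(as.integer(seed))
  eps <- rnorm(n_days, 0, sigma)
  w <- numeric(n_days)
  hist <- init
  clipped <- 0L
  for (t in seq_len(n_days)) {
    w[t] <- gamma0 + gamma1 * c_path[t] +
      (if (m > 0L) sum(phi * hist) else 0) + eps[t]
    if (w[t] < 0 || w[t] > 1) {
      clipped <- clipped + 1L
      w[t] <- min(max(w[t], 0), 1)
    }
    if (m > 0L) hist <- c(w[t], hist[-m])
  }
  if (clipped > 0L)
    warning(clipped, " fatality-rate draw(s) clipped to [0, 1]",
            call. = FALSE)
  cum_tests <- cummax(round(tests_path))
  cum_pos <- cummax(round(c_path * cum_tests))
  cum_deaths <- numeric(n_days)
  for (t in seq_len(n_days)) {
    raw <- if (t > lag_days) round(w[t] * cum_pos[t - lag_days]) else 0
    cum_deaths[t] <- if (t > 1L) max(cum_deaths[t - 1L], raw) else raw
  }
  out <- daily_epidemic_series(start_date + seq_len(n_days) - 1L,
                               cum_pos, cum_tests, cum_deaths)
  attr(out, "truth") <- list(gamma0 = gamma0, gamma1 = gamma1, phi = phi,
                             sigma = sigma, w = w, infection_path = c_path,
                             lag_days = as.integer(lag_days),
                             seed = as.integer(seed))
  out
}

#' Florida reference tables for the decision stage
#'
#' The published Florida summaries used by the scenario machinery:
#' per-infection-rate Delta-NB means, SDs, central 95% percentiles and
#' P(Delta-NB > 0) for the unadjusted and relief-adjusted income measures,
#' the three policy-scenario probability matrices over incremental
#' infection rates 10/15/20/25%, and the default cost and income
#' assumptions. These are fixture inputs for the look-up-table stage and
#' its golden tests; they are reference values, not computed output.
#'
#' @return A list with elements \code{delta_nb} (data.frame), \code{scenarios}
#'   (named list of \code{\link{scenario_matrix}}), \code{costs}
#'   (\code{\link{cost_assumptions}}) and \code{income}
#'   (\code{\link{income_assumptions}}).
#' @export
fixture_florida_tables <- function() {
  delta_nb <- data.frame(
    income = rep(c("unadjusted", "adjusted"), each = 4L),
    rate = rep(c(10, 15, 20, 25), 2L),
    mean = c(42964, 27295, 9404, -8564,
             48666, 32982, 15066, -2914),
    sd = c(13186, 20877, 28086, 36438,
           13186, 20872, 28085, 36438),
    q2.5 = c(17654, -13685, -44606, -80608,
             23256, -7920, -38876, -75048),
    q97.5 = c(68504, 67915, 63870, 61562,
              74228, 73731, 69423, 67205),
    p_positive = c(0.9998, 0.8996, 0.6344, 0.4104,
                   0.9998, 0.9394, 0.7072, 0.4738))
  scenarios <- list(
    scenario_1 = scenario_matrix(rbind(c(0.5, 0.3, 0.1, 0.1),
                                       c(0.2, 0.4, 0.2, 0.2),
                                       c(0.1, 0.2, 0.4, 0.3))),
    scenario_2 = scenario_matrix(rbind(c(0.3, 0.3, 0.3, 0.1),
                                       c(0.2, 0.3, 0.3, 0.2),
                                       c(0.1, 0.2, 0.4, 0.3))),
    scenario_3 = scenario_matrix(rbind(c(0.2, 0.4, 0.3, 0.1),
                                       c(0.1, 0.2, 0.4, 0.3),
                                       c(0.0, 0.1, 0.4, 0.5))))
  list(delta_nb = delta_nb, scenarios = scenarios,
       costs = cost_assumptions(), income = income_assumptions())
}
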