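# Monetary conversion: employment draws -> per-capita income benefit;
# fatality-rate draws -> medical + fatality cost.
#
# Cost model, relative to a baseline (w0, c0) observed on the decision day:
#   medical:   dl_Si = (w0*c0 - w*c) * C_Si,  i in {1, 2, 3}
#   fatality:  dl_D  = (w*c - w0*c0) * C_D
#   total      = (w*c - w0*c0) * (C_D - C_S1 - C_S2 - C_S3)
# With the default assumptions the composite multiplier is exactly
# $6,968,000 = 7,000,000 - 2,000 - 15,000 - 15,000.

#' Cost assumptions
#'
#' @param c_s1 Testing/treatment cost for an uninfected symptomatic person
#'   (dollars; default 2,000).
#' @param c_s2 Treatment cost for an infected patient who recovers
#'   (default 15,000).
#' @param c_s3 Treatment cost for an infected patient who dies
#'   (default 15,000, set equal to \code{c_s2}).
#' @param c_d Value-of-statistical-life fatality cost (default 7,000,000).
#' @param w0 Baseline death rate as a fraction (default 0.0348, the Florida
#'   value on 30 June 2020).
#' @param c0 Baseline infection rate as a fraction (default 0.0784, same
#'   baseline).
#' @return An object of class \code{cost_assumptions}.
#' @export
cost_assumptions <- function(c_s1 = 2000, c_s2 = 15000, c_s3 = 15000,
                             c_d = 7e6, w0 = 0.0348, c0 = 0.0784) {
  if (any(c(c_s1, c_s2, c_s3, c_d) < 0))
    stop_input("costs must be non-negative")
  if (c_d <= c_s1 + c_s2 + c_s3)
    stop_input("the fatality cost must exceed the summed medical costs")
  if (w0 < 0 || w0 > 1 || c0 < 0 || c0 > 1)
    stop_input("baseline rates must be fractions in [0, 1]")
  structure(list(c_s1 = c_s1, c_s2 = c_s2, c_s3 = c_s3, c_d = c_d,
                 w0 = w0, c0 = c0),
            class = "cost_assumptions")
}

#' Income assumptions
#'
#' @param annual Annual per-capita personal income in dollars (default
#'   52,426, Florida 2019).
#' @param adjusted Relief-adjusted per-capita income including federal
#'   transfer payments (default 58,371).
#' @return An object of class \code{income_assumptions}.
#' @export
income_assumptions <- function(annual = 52426, adjusted = 58371) {
  if (annual <= 0 || adjusted <= 0) stop_input("incomes must be positive")
  if (adjusted < annual)
    stop_input("adjusted income must be at least the unadjusted income")
  structure(list(annual = annual, adjusted = adjusted),
            class = "income_assumptions")
}

#' Income draws from employment draws
#'
#' Scales one-step-ahead percent-employed draws against an annual per-capita
#' income: each dollar draw is (employment / 100) * income. Negative
#' employment draws (possible in the normal predictive tails) are clipped to
#' zero with a warning.
#'
#' @param emp_draws Employment draws on the 0--100 scale
#'   (\code{\link{predict_next}} output or plain numeric).
#' @param income Dollars per capita (> 0).
#' @return Numeric dollar draws of class \code{monetary_draws} with
#'   \code{label = "benefit"}.
#' @export
income_from_employment <- function(emp_draws, income) {
  if (income <= 0) stop_input("`income` must be positive")
  emp <- as.numeric(emp_draws)
  if (any(emp < 0)) {
    warning(sum(emp < 0), " negative employment draw(s) clipped to 0",
            call. = FALSE)
    emp[emp < 0] <- 0
  }
  structure(emp / 100 * income, class = "monetary_draws",
            label = "benefit", income = income)
}

#' Cost components at a given death and infection rate
#'
#' @param w Death rate (fraction).
#' @param c Infection rate (fraction).
#' @param assumptions A \code{\link{cost_assumptions}}.
#' @return Named vector \code{dl_s1, dl_s2, dl_s3, dl_d} in dollars.
#' @export
component_costs <- function(w, c, assumptions = cost_assumptions()) {
  a <- assumptions
  if (any(w < 0 | w > 1) || any(c < 0 | c > 1))
    stop_input("`w` and `c` must be fractions in [0, 1]")
  base <- a$w0 * a$c0
  cur <- w * c
  c(dl_s1 = (base - cur) * a$c_s1,
    dl_s2 = (base - cur) * a$c_s2,
    dl_s3 = (base - cur) * a$c_s3,
    dl_d = (cur - base) * a$c_d)
}

#' Composite cost multiplier
#'
#' \code{c_d - c_s1 - c_s2 - c_s3}; exactly 6,968,000 under the defaults.
#' @param assumptions A \code{\link{cost_assumptions}}.
#' @export
cost_multiplier <- function(assumptions = cost_assumptions()) {
  with(assumptions, c_d - c_s1 - c_s2 - c_s3)
}

#' Total incremental cost draws
#'
#' Per death-rate draw: \code{(w * c - w0 * c0) * (c_d - c_s1 - c_s2 -
#' c_s3)}. Draws may be negative when the scenario falls below the baseline
#' product.
#'
#' @param w_draws Death-rate draws (fractions).
#' @param c Scenario infection rate (fraction).
#' @param assumptions A \code{\link{cost_assumptions}}.
#' @return Dollar draws of class \code{monetary_draws} with
#'   \code{label = "cost"}.
#' @export
total_cost <- function(w_draws, c, assumptions = cost_assumptions()) {
  a <- assumptions
  if (c < 0 || c > 1) stop_input("`c` must be a fraction in [0, 1]")
  w <- as.numeric(w_draws)
  structure((w * c - a$w0 * a$c0) * cost_multiplier(a),
            class = "monetary_draws", label = "cost", scenario_rate = c)
}
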