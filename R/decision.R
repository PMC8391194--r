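# The net-benefit decision rule and policy-scenario look-up tables.
#
# Delta-NB = benefit - cost, simulated by drawing independently from normal
# approximations to the benefit and cost predictive distributions (both are
# approximately normal; their MCMC means and SDs are sufficient). The rule:
# reopen when mean Delta-NB > 0 and P(Delta-NB > 0) >= T.
#
# Scenario tables: policy j induces incremental infection rate k with
# probability pi_jk. E(B_j) = sum_k pi_jk * E(B_jk). P_j is computed from
# the pi-weighted SUM of independent per-rate draws (one draw per rate per
# index, weighted and summed), whose closed form is
#   Phi( sum_k pi_jk mu_k / sqrt(sum_k pi_jk^2 sigma_k^2) ).
# A mixture reading (sum_k pi_jk * P_k) is exposed behind
# `mechanism = "mixture"` but is not the default: it is not consistent with
# the weighted-expectation construction of E(B_j).

normal_params <- function(x, what) {
  if (is.numeric(x) && length(x) > 1L && is.null(names(x))) {
    return(c(mean = mean(x), sd = sd(x)))
  }
  x <- unlist(x)
  if (!all(c("mean", "sd") %in% names(x)))
    stop_input("`", what, "` must be draws or a (mean, sd) pair")
  c(mean = unname(x["mean"]), sd = unname(x["sd"]))
}

#' Distribution of the change in net benefit
#'
#' Draws \code{n_draws} independent samples from normal approximations to
#' the benefit and cost distributions and subtracts them. Inputs may be
#' vectors of monetary draws (their mean/SD are used) or named
#' \code{c(mean=, sd=)} pairs.
#'
#' @param benefit,cost Monetary draws or \code{c(mean=, sd=)}.
#' @param n_draws Number of Delta-NB draws (default 5,000).
#' @param seed Integer seed.
#' @param scenario_rate,income_label Optional provenance tags carried into
#'   the summary.
#' @return An object of class \code{nb_summary}: a list with \code{mean},
#'   \code{sd}, \code{q2.5}, \code{q97.5}, \code{p_positive},
#'   \code{n_draws}, and the provenance tags.
#' @export
delta_nb <- function(benefit, cost, n_draws = 5000L, seed = 1L,
                     scenario_rate = NA_real_, income_label = NA_character_) {
  n_draws <- as.integer(n_draws)
  if (n_draws < 2L) stop_input("`n_draws` must be at least 2")
  b <- normal_params(benefit, "benefit")
  co <- normal_params(cost, "cost")
  if (b["sd"] < 0 || co["sd"] < 0) stop_input("SDs must be non-negative")
  set.seed(as.integer(seed))
  nb <- rnorm(n_draws, b["mean"], b["sd"]) - rnorm(n_draws, co["mean"], co["sd"])
  q <- unname(quantile(nb, c(0.025, 0.975)))
  structure(list(mean = mean(nb), sd = sd(nb), q2.5 = q[1L], q97.5 = q[2L],
                 p_positive = mean(nb > 0), n_draws = n_draws,
                 scenario_rate = scenario_rate, income_label = income_label),
            class = "nb_summary")
}

#' @export
print.nb_summary <- function(x, ...) {
  cat(sprintf(
    "Delta-NB summary (%d draws%s): mean %s, SD %s, 95%% [%s, %s], P(>0) = %.4f\n",
    x$n_draws,
    if (!is.na(x$scenario_rate)) sprintf(", infection rate %g%%",
                                         100 * x$scenario_rate) else "",
    format(round(x$mean), big.mark = ","), format(round(x$sd), big.mark = ","),
    format(round(x$q2.5), big.mark = ","), format(round(x$q97.5), big.mark = ","),
    x$p_positive))
  invisible(x)
}

#' The reopening decision rule
#'
#' Reopen ("decremental suppression") if and only if the mean change in net
#' benefit is positive AND the probability of a positive change meets the
#' risk threshold \code{T}.
#'
#' @param summary An \code{\link{nb_summary}} (or any list with \code{mean}
#'   and \code{p_positive}).
#' @param T Threshold probability in (0, 1]; larger values encode more risk
#'   aversion.
#' @return \code{"reopen"} or \code{"do_not_reopen"}.
#' @export
decide <- function(summary, T = 0.9) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0 || T > 1)
    stop_input("`T` must be a single probability in (0, 1]")
  if (summary$mean > 0 && summary$p_positive >= T) "reopen" else "do_not_reopen"
}

#' Scenario matrix of policy-conditional infection-rate probabilities
#'
#' @param probs Numeric matrix, one row per policy, one column per
#'   incremental infection rate; each row must sum to 1.
#' @param policies Policy labels in order of increasing disruption (the
#'   order used to break expected-benefit ties toward the less disruptive
#'   policy).
#' @param rates Incremental infection rates in percent.
#' @return A matrix of class \code{scenario_matrix}.
#' @export
scenario_matrix <- function(probs,
                            policies = c("Minor", "Moderate", "Major"),
                            rates = c(10, 15, 20, 25)) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(policies) || ncol(probs) != length(rates))
    stop_input("`probs` must be policies x rates")
  if (any(probs < 0)) stop_input("probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop_input("each policy row must sum to 1")
  dimnames(probs) <- list(policies, as.character(rates))
  attr(probs, "rates") <- rates
  class(probs) <- c("scenario_matrix", class(probs))
  probs
}

check_row <- function(row, rates) {
  if (length(row) != length(rates))
    stop_input("probability row and rate grid lengths differ")
  if (any(row < 0) || abs(sum(row) - 1) > 1e-9)
    stop_input("probability row must be non-negative and sum to 1")
  invisible(row)
}

#' Expected incremental infection rate of a policy row
#'
#' @param row Probability weights over the rate grid (must sum to 1).
#' @param rates Rate grid in percent (default \code{c(10, 15, 20, 25)}).
#' @return The probability-weighted rate, in percent.
#' @export
expected_infection_rate <- function(row, rates = c(10, 15, 20, 25)) {
  check_row(row, rates)
  sum(row * rates)
}

#' Expected net benefit of a policy
#'
#' \code{sum_k pi_jk * mean_k}, rounded to the nearest dollar.
#'
#' @param nb_means Mean Delta-NB per rate, aligned to \code{rates} (or named
#'   by them).
#' @param row Probability weights over the rate grid.
#' @param rates Rate grid in percent.
#' @return Expected benefit in whole dollars.
#' @export
scenario_expected_benefit <- function(nb_means, row,
                                      rates = c(10, 15, 20, 25)) {
  check_row(row, rates)
  if (!is.null(names(nb_means))) {
    miss <- setdiff(as.character(rates[row > 0]), names(nb_means))
    if (length(miss))
      stop_input("missing Delta-NB mean for rate(s): ",
                 paste(miss, collapse = ", "))
    nb_means <- nb_means[as.character(rates)]
  }
  if (length(nb_means) != length(rates) || anyNA(nb_means[row > 0]))
    stop_input("a Delta-NB mean is required for every rate with weight > 0")
  nb_means[is.na(nb_means)] <- 0
  round(sum(row * nb_means))
}

#' Probability that a policy's net benefit is positive
#'
#' Default mechanism (\code{"weighted_sum"}): for each of \code{n_draws}
#' indices, draw one normal value per rate from its (mean, SD), form the
#' pi-weighted sum across rates, and report the fraction of positive sums.
#' \code{analytic = TRUE} replaces sampling with the closed form
#' \code{pnorm(sum(pi * mu) / sqrt(sum(pi^2 * sigma^2)))}. The
#' \code{"mixture"} mechanism instead draws the rate first
#' (probability pi) and then one value from that rate's normal.
#'
#' @param nb_means,nb_sds Per-rate Delta-NB means and SDs.
#' @param row Probability weights over the rate grid.
#' @param n_draws Monte-Carlo draws (default 5,000).
#' @param seed Integer seed.
#' @param rates Rate grid in percent.
#' @param mechanism \code{"weighted_sum"} (default) or \code{"mixture"}.
#' @param analytic Use the closed form instead of sampling
#'   (weighted-sum mechanism only).
#' @return Probability in [0, 1].
#' @export
scenario_prob_positive <- function(nb_means, nb_sds, row, n_draws = 5000L,
                                   seed = 1L, rates = c(10, 15, 20, 25),
                                   mechanism = c("weighted_sum", "mixture"),
                                   analytic = FALSE) {
  mechanism <- match.arg(mechanism)
  check_row(row, rates)
  if (any(nb_sds < 0)) stop_input("SDs must be non-negative")
  if (length(nb_means) != length(rates) || length(nb_sds) != length(rates))
    stop_input("means and SDs must align with the rate grid")
  if (analytic) {
    if (mechanism == "mixture") {
      return(sum(row * pnorm(nb_means / pmax(nb_sds, .Machine$double.eps))))
    }
    s <- sqrt(sum(row^2 * nb_sds^2))
    if (s == 0) return(as.numeric(sum(row * nb_means) > 0))
    return(pnorm(sum(row * nb_means) / s))
  }
  n_draws <- as.integer(n_draws)
  if (n_draws < 2L) stop_input("`n_draws` must be at least 2")
  set.seed(as.integer(seed))
  if (mechanism == "weighted_sum") {
    draws <- matrix(rnorm(n_draws * length(rates), rep(nb_means, each = n_draws),
                          rep(nb_sds, each = n_draws)),
                    nrow = n_draws)
    sums <- drop(draws %*% row)
    return(mean(sums > 0))
  }
  comp <- sample.int(length(rates), n_draws, replace = TRUE, prob = row)
  mean(rnorm(n_draws, nb_means[comp], nb_sds[comp]) > 0)
}

#' Policy look-up table for a set of scenarios
#'
#' For each scenario matrix and each policy row, computes the expected net
#' benefit E(B_j) and the probability of a positive net benefit P_j, then
#' applies the two choice rules: the risk-neutral choice is the policy with
#' the highest E(B_j); the risk-averse choice is the highest-E(B_j) policy
#' among those with P_j > T, or \code{"none"} when no policy qualifies.
#' Ties in E(B_j) are broken toward the policy listed earlier in the
#' scenario matrix (the less disruptive reopening).
#'
#' @param nb_summaries A \code{data.frame} with columns \code{rate},
#'   \code{mean}, \code{sd} (one row per rate on the grid), or a list of
#'   \code{\link{nb_summary}} objects carrying \code{scenario_rate}.
#' @param scenarios A named list of \code{\link{scenario_matrix}} objects
#'   sharing one rate grid.
#' @param T Risk-aversion threshold in (0, 1].
#' @param n_draws Monte-Carlo draws for each P_j (ignored when
#'   \code{analytic}).
#' @param seed Integer seed.
#' @param analytic Use the closed-form P_j.
#' @return A \code{data.frame} of class \code{decision_table} with columns
#'   \code{scenario}, \code{policy}, \code{expected_benefit}, \code{p_positive};
#'   per-scenario choices are attached as attribute \code{"choices"}.
#' @export
build_lookup_table <- function(nb_summaries, scenarios, T = 0.9,
                               n_draws = 5000L, seed = 1L, analytic = FALSE) {
  if (!length(scenarios)) stop_input("`scenarios` must be a non-empty list")
  if (is.list(nb_summaries) && !is.data.frame(nb_summaries)) {
    nb_summaries <- data.frame(
      rate = vapply(nb_summaries, `[[`, numeric(1L), "scenario_rate"),
      mean = vapply(nb_summaries, `[[`, numeric(1L), "mean"),
      sd = vapply(nb_summaries, `[[`, numeric(1L), "sd"))
  }
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  rows <- list()
  choices <- list()
  for (sc in names(scenarios)) {
    m <- scenarios[[sc]]
    rates <- attr(m, "rates")
    ord <- match(rates, nb_summaries$rate)
    if (anyNA(ord))
      stop_input("Delta-NB summaries missing for rate(s): ",
                 paste(rates[is.na(ord)], collapse = ", "))
    mu <- nb_summaries$mean[ord]
    sg <- nb_summaries$sd[ord]
    eb <- pj <- numeric(nrow(m))
    for (j in seq_len(nrow(m))) {
      eb[j] <- scenario_expected_benefit(mu, m[j, ], rates)
      pj[j] <- scenario_prob_positive(mu, sg, m[j, ], n_draws,
                                      seed = seed + j, rates = rates,
                                      analytic = analytic)
    }
    # which.max returns the first maximum: the earlier (less disruptive)
    # policy wins ties
    rn <- rownames(m)[which.max(eb)]
    ok <- pj > T
    ra <- if (any(ok)) rownames(m)[which(ok)[which.max(eb[ok])]] else "none"
    rows[[sc]] <- data.frame(scenario = sc, policy = rownames(m),
                             expected_benefit = eb,
                             p_positive = round(pj, 4))
    choices[[sc]] <- list(risk_neutral = rn, risk_averse = ra, T = T)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "choices") <- choices
  class(out) <- c("decision_table", "data.frame")
  out
}

#' @export
print.decision_table <- function(x, ...) {
  print.data.frame(as.data.frame(x), row.names = FALSE)
  for (sc in names(attr(x, "choices"))) {
    ch <- attr(x, "choices")[[sc]]
    cat(sprintf("%s: risk-neutral -> %s; risk-averse (T = %g) -> %s\n",
                sc, ch$risk_neutral, ch$T, ch$risk_averse))
  }
  invisible(x)
}
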