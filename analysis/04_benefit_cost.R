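#!/usr/bin/env Rscript
# Stage 4: convert the fitted models into money. For each hypothetical
# infection rate (10%, 15%, 20%, 25%) form the one-step-ahead predictive
# distributions of percent employed and of the fatality rate, convert to
# per-capita income benefit (E/100 x annual income, unadjusted and
# relief-adjusted) and to medical + fatality cost
# ((w c - w0 c0) x $6,968,000), and summarize the Delta-NB distribution
# per rate and income measure with 5000 draws.

library(nbdecide)

emp <- read_series_csv("results/employment_panel.csv", "weekly")
epi <- read_series_csv("results/epidemic_panel.csv", "daily")
emp_order <- sum(grepl("^ar", read.csv("results/posterior_employment.csv")$parameter))
fat_order <- sum(grepl("^ar", read.csv("results/posterior_fatality.csv")$parameter))

mcmc <- mcmc_config(seed = 7L)
emp_spec <- arx_spec(emp_order, exog_names = c("infection_rate", "dummy"))
emp_fit <- fit_arx(emp$employment_pct,
                   as.matrix(emp[, c("infection_rate", "dummy")]),
                   emp_spec, mcmc)
w <- compute_death_rate(epi, lag_days = 7)
c_daily <- compute_infection_rate(epi)
cw <- c_daily$value[match(w$date, c_daily$date)]
fat_spec <- arx_spec(fat_order, exog_names = "infection_rate")
fat_fit <- fit_arx(w$value, cbind(infection_rate = cw), fat_spec, mcmc)

income <- income_assumptions()
# baseline (w0, c0): the observed rates on the last simulated day
costs <- cost_assumptions(w0 = tail(w$value, 1),
                          c0 = tail(c_daily$value, 1))
message(sprintf("Baseline: w0 = %.4f, c0 = %.4f; composite multiplier $%s",
                costs$w0, costs$c0,
                format(cost_multiplier(costs), big.mark = ",")))

rates <- c(0.10, 0.15, 0.20, 0.25)
# lags ordered most recent first
emp_lags <- emp$employment_pct[nrow(emp) - seq_len(emp_order) + 1]
fat_lags <- w$value[nrow(w) - seq_len(fat_order) + 1]

rows <- list()
for (r in rates) {
  emp_draws <- predict_next(emp_fit, emp_lags,
                            c(infection_rate = r, dummy = 1),
                            seed = 1000 + round(100 * r))
  w_draws <- predict_next(fat_fit, fat_lags, c(infection_rate = r),
                          seed = 2000 + round(100 * r))
  cost_draws <- total_cost(as.numeric(w_draws), r, costs)
  for (inc in c("unadjusted", "adjusted")) {
    money <- if (inc == "unadjusted") income$annual else income$adjusted
    ben <- income_from_employment(emp_draws, money)
    d <- delta_nb(ben, cost_draws, n_draws = 5000,
                  seed = 3000 + round(100 * r),
                  scenario_rate = r, income_label = inc)
    print(d)
    rows[[length(rows) + 1]] <- data.frame(
      income = inc, rate = 100 * r, mean = round(d$mean), sd = round(d$sd),
      q2.5 = round(d$q2.5), q97.5 = round(d$q97.5),
      p_positive = round(d$p_positive, 4))
  }
}
tab <- do.call(rbind, rows)
tab <- tab[order(tab$income, tab$rate), ]
write.csv(tab, "results/delta_nb_summaries.csv", row.names = FALSE,
          quote = FALSE)
message("Wrote results/delta_nb_summaries.csv")
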