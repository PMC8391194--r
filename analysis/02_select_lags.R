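#!/usr/bin/env Rscript
# Stage 2: choose the autoregressive order for both models by posterior
# model probability (candidates 1..7 for employment, 1..4 for the daily
# fatality rate), scoring every candidate on a common observation window.

library(nbdecide)

emp <- read_series_csv("results/employment_panel.csv", "weekly")
epi <- read_series_csv("results/epidemic_panel.csv", "daily")

mcmc <- mcmc_config(iterations = 4000, burn_in = 1000, seed = 11L)

message("Scoring employment lag candidates 1..7...")
emp_cmp <- suppressWarnings(select_lag(
  emp$employment_pct,
  as.matrix(emp[, c("infection_rate", "dummy")]),
  p_max = 7, mcmc = mcmc))
print(emp_cmp)
write_comparison_csv(emp_cmp, "results/lag_selection_employment.csv")

message("Constructing daily fatality-rate series (7-day case lag)...")
w <- compute_death_rate(epi, lag_days = 7)
c_daily <- compute_infection_rate(epi)
cw <- c_daily$value[match(w$date, c_daily$date)]

message("Scoring fatality-rate lag candidates 1..4...")
fat_cmp <- suppressWarnings(select_lag(
  w$value, cbind(infection_rate = cw), p_max = 4, mcmc = mcmc))
print(fat_cmp)
write_comparison_csv(fat_cmp, "results/lag_selection_fatality.csv")

message("Selected orders: employment p = ", attr(emp_cmp, "best"),
        ", fatality m = ", attr(fat_cmp, "best"))
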