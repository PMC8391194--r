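#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study panels.
#
# Real analyses of this kind start from a weekly percent-employed series
# (here: fourteen years including one recession window and a pandemic
# window) and a daily epidemic count panel. Neither raw source is
# redistributable, so the panels are simulated from the two ARX processes
# the models assume, with ground truth saved alongside so later stages can
# be validated against it.

library(nbdecide)

dir.create("results", showWarnings = FALSE)
seed <- 20200630L

message("Generating weekly employment panel (695 weeks, ARX(4))...")
emp <- gen_employment_panel(seed = seed)
write_series_csv(emp, "results/employment_panel.csv")

message("Generating daily epidemic count panel (120 days, AR(2) rate)...")
epi <- suppressWarnings(gen_epidemic_panel(
  n_days = 120,
  infection_path = 0.02 + 0.06 * (1 - exp(-(1:120) / 40)),
  seed = seed + 1L))
write_series_csv(epi, "results/epidemic_panel.csv")

truths <- list(employment = attr(emp, "truth"),
               epidemic = attr(epi, "truth"))
jsonlite::write_json(truths, "results/panel_truth.json",
                     auto_unbox = TRUE, digits = NA)

message("Employment: ", nrow(emp), " weeks, mean percent employed ",
        round(mean(emp$employment_pct), 2))
message("Epidemic: ", nrow(epi), " days, final positivity ",
        round(tail(epi$cum_positives / epi$cum_tests, 1), 4),
        ", final deaths ", tail(epi$cum_deaths, 1))
message("Wrote results/employment_panel.csv, results/epidemic_panel.csv, ",
        "results/panel_truth.json")
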