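#!/usr/bin/env Rscript
# Stage 5: the decision layer. Applies the reopening rule to the Delta-NB
# summaries from stage 4 and builds the policy look-up tables for the
# three scenario matrices, under a risk-averse threshold T = 0.90. The
# same machinery is then run on the published Florida reference summaries,
# which reproduces the published look-up table.

library(nbdecide)

T_threshold <- 0.90
nb <- read.csv("results/delta_nb_summaries.csv")
un <- nb[nb$income == "unadjusted", ]

message("Per-rate decisions (unadjusted income, T = ", T_threshold, "):")
for (i in seq_len(nrow(un))) {
  verdict <- decide(list(mean = un$mean[i], p_positive = un$p_positive[i]),
                    T = T_threshold)
  message(sprintf("  %2.0f%% infection rate: mean $%s, P(>0) = %.4f -> %s",
                  un$rate[i], format(un$mean[i], big.mark = ","),
                  un$p_positive[i], verdict))
}

fl <- fixture_florida_tables()
message("\nScenario look-up table from the stage-4 simulated summaries:")
tab <- build_lookup_table(un[, c("rate", "mean", "sd")], fl$scenarios,
                          T = T_threshold, n_draws = 1e5, seed = 42)
print(tab)
write.csv(as.data.frame(tab), "results/decision_table_simulated.csv",
          row.names = FALSE, quote = FALSE)

message("\nScenario look-up table from the published reference summaries:")
ref <- fl$delta_nb[fl$delta_nb$income == "unadjusted", c("rate", "mean", "sd")]
ref_tab <- build_lookup_table(ref, fl$scenarios, T = T_threshold,
                              n_draws = 1e5, seed = 42)
print(ref_tab)
write.csv(as.data.frame(ref_tab), "results/decision_table_reference.csv",
          row.names = FALSE, quote = FALSE)
message("Wrote results/decision_table_simulated.csv and ",
        "results/decision_table_reference.csv")
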