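#!/usr/bin/env Rscript
# Stage 3 — the repeated-measures statistical battery on the simulated
# study: descriptives, RM-ANOVA with Greenhouse-Geisser correction,
# Bonferroni-corrected paired post hocs with pooled-SD Cohen's d, and
# pooled Pearson correlations between metrics and scales.
suppressPackageStartupMessages(library(gazestate))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

study <- simulate_study(simulation_spec(seed = seed))
bt <- run_stats_battery(study)
readr::write_csv(bt$descriptives, "results/descriptives.csv")
readr::write_csv(bt$anova, "results/anova.csv")
readr::write_csv(bt$posthoc, "results/posthoc.csv")
readr::write_csv(bt$correlations, "results/correlations.csv")

cat("RM-ANOVA (GG-corrected):\n")
print(as.data.frame(bt$anova[, c("measure", "F", "df1", "df2", "eps_gg",
                                 "p_gg", "stars", "eta_p2")]), digits = 3)
cat("\nIL correlations with eye-tracking metrics:\n")
print(as.data.frame(bt$correlations[bt$correlations$scale == "il", ]),
      digits = 2)
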