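#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study: 26 participants x 3 cognitive
# states, a 100-step cumulative metric series per session plus
# questionnaire scores, calibrated to the study's descriptive targets.
suppressPackageStartupMessages(library(gazestate))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

study <- simulate_study(simulation_spec(seed = seed))
readr::write_csv(study$series, "results/series.csv")
readr::write_csv(study$aggregates, "results/aggregates.csv")
readr::write_csv(study$questionnaires, "results/questionnaires.csv")

n_sessions <- nrow(unique(study$series[, c("participant_id", "state_label")]))
cat(sprintf("sessions: %d, time steps: %d (%d per class)\n",
            n_sessions, nrow(study$series),
            sum(study$series$state_label == 0)))
desc <- dplyr::summarise(
  dplyr::group_by(study$aggregates, measure, state),
  mean = mean(value), sd = sd(value), .groups = "drop")
print(as.data.frame(desc), digits = 4)
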