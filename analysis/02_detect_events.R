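#!/usr/bin/env Rscript
# Stage 2 — I-VT event detection on simulated gaze streams: plant
# fixation/saccade events in a noise-free 120 Hz stream, detect them with
# the velocity-threshold algorithm, attribute them to AOIs and
# accumulate the cumulative metric series.
suppressPackageStartupMessages(library(gazestate))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

gs <- simulate_gaze_stream(duration_s = 10, seed = seed, fix_jitter_v = 0)
write_gaze_csv(gs$samples, "results/gaze_stream.csv")
ev <- detect_gaze_events(gs$samples)
cat(sprintf("planted %d events, detected %d (%d fixations, %d saccades)\n",
            nrow(gs$ground_truth), nrow(ev),
            sum(ev$kind == "fixation"), sum(ev$kind == "saccade")))
cat(sprintf("max boundary error: %.3f ms\n",
            1000 * max(abs(ev$t_start - gs$ground_truth$t_start))))

aois <- default_aoi_layout()
write_aoi_json(aois, "results/aoi_layout.json")
ev <- attribute_events(ev, gs$samples, aois)
write_events_csv(ev, "results/events.csv")
met <- accumulate_metrics(ev, clock = seq(0, 10, by = 0.1))
write_metrics_csv(met, "results/metrics.csv")
cat("per-AOI attribution:\n")
print(table(ev$aoi_id))
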