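# shared fixtures built in code

# a gaze stream with a hand-planted pair-velocity schedule: each entry of
# `v` (deg/s) drives one consecutive sample pair, rotating in a plane
stream_from_velocities <- function(v, rate = 120) {
  dt <- 1 / rate
  ang <- cumsum(c(0, v * dt)) * pi / 180
  tibble::tibble(t = (seq_along(ang) - 1) * dt,
                 dir_x = cos(ang), dir_y = sin(ang), dir_z = 0)
}

# brute-force maximal-run scan used as the segmentation oracle
brute_force_runs <- function(labels) {
  out <- list()
  i <- 1
  while (i <= length(labels)) {
    j <- i
    while (j < length(labels) && labels[j + 1] == labels[i]) j <- j + 1
    if (labels[i] != "unclassified") {
      out[[length(out) + 1]] <- c(start = i, end = j, kind = labels[i])
    }
    i <- j + 1
  }
  out
}

# small calibrated study reused across classifier tests
tiny_study <- function(n = 6, L = 60, seed = 41) {
  simulate_study(simulation_spec(n_participants = n, series_length = L,
                                 seed = seed))
}

# printed descriptive statistics and post hoc effect sizes used by the
# effect-size reproduction checks: mean/sd per state and the published d
printed_effect_sizes <- function() {
  tibble::tribble(
    ~measure, ~pair, ~m1, ~s1, ~m2, ~s2, ~d_printed, ~digits,
    "nasa_tlx", "distraction vs immersion", 6.019, 2.554, 5.256, 2.290, 0.314, 3,
    "nasa_tlx", "distraction vs overload", 6.019, 2.554, 8.974, 5.393, 0.700, 3,
    "nasa_tlx", "immersion vs overload", 5.256, 2.290, 8.974, 5.393, 0.897, 3,
    "fss", "distraction vs immersion", 2.992, 1.007, 4.269, 0.633, 1.51, 2,
    "fss", "distraction vs overload", 2.992, 1.007, 3.804, 0.541, 1.00, 2,
    "fss", "immersion vs overload", 4.269, 0.633, 3.804, 0.541, 0.79, 2,
    "distractibility", "distraction vs immersion", 5.45, 1.16, 2.25, 0.93, 3.04, 2,
    "distractibility", "distraction vs overload", 5.45, 1.16, 2.66, 0.94, 2.64, 2,
    "distractibility", "immersion vs overload", 2.25, 0.93, 2.66, 0.94, 0.44, 2,
    "fixation_duration", "distraction vs immersion", 12.98, 7.73, 6.73, 3.38, 1.05, 2,
    "fixation_duration", "distraction vs overload", 12.98, 7.73, 14.96, 6.31, 0.28, 2,
    "fixation_duration", "immersion vs overload", 6.73, 3.38, 14.96, 6.31, 1.62, 2,
    "fixation_count", "distraction vs immersion", 41.42, 21.58, 24.23, 9.98, 1.02, 2,
    "fixation_count", "distraction vs overload", 41.42, 21.58, 56.46, 21.39, 0.70, 2,
    "fixation_count", "immersion vs overload", 24.23, 9.98, 56.46, 21.39, 1.93, 2,
    "saccade_duration", "distraction vs immersion", 1.47, 1.09, 1.02, 0.73, 0.49, 2,
    "saccade_duration", "distraction vs overload", 1.47, 1.09, 3.85, 3.26, 0.98, 2,
    "saccade_duration", "immersion vs overload", 1.02, 0.73, 3.85, 3.26, 1.20, 2,
    "saccade_count", "distraction vs immersion", 23.58, 16.43, 17.96, 12.89, 0.38, 2,
    "saccade_count", "distraction vs overload", 23.58, 16.43, 60.42, 47.87, 1.03, 2,
    "saccade_count", "immersion vs overload", 17.96, 12.89, 60.42, 47.87, 1.21, 2
  )
}
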