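#' State labels used throughout the package
#'
#' Cognitive overload = 0, immersion = 1, distraction = 2.
#' @keywords internal
state_levels <- c(overload = 0L, immersion = 1L, distraction = 2L)

#' Calibration targets for the synthetic generator
#'
#' Per-state means and SDs of the four per-session eye-tracking
#' aggregates (cumulative fixation/saccade duration in seconds and
#' counts) and of the questionnaire scales (NASA-TLX on 0-20, FSS on
#' 1-5, Distractibility on 1-7, and the intrinsic/extraneous/germane
#' cognitive-load subscales on 0-10). These are the study conditions the
#' generator emulates for the 26-participant, three-state design.
#'
#' @return Tibble with columns `measure`, `kind` (`"metric"` or
#'   `"scale"`), `state` (`"overload"`, `"immersion"`, `"distraction"`),
#'   `mean`, `sd`, `lower`, `upper` (support bounds used when drawing).
#' @export
reference_targets <- function() {
  row <- function(measure, kind, lo, up, m_ov, s_ov, m_im, s_im, m_di, s_di) {
    tibble::tibble(measure = measure, kind = kind,
                   state = c("overload", "immersion", "distraction"),
                   mean = c(m_ov, m_im, m_di), sd = c(s_ov, s_im, s_di),
                   lower = lo, upper = up)
  }
  dplyr::bind_rows(
    row("fixation_duration", "metric", 0, Inf, 14.96, 6.31, 6.73, 3.38, 12.98, 7.73),
    row("fixation_count",    "metric", 0, Inf, 56.46, 21.39, 24.23, 9.98, 41.42, 21.58),
    row("saccade_duration",  "metric", 0, Inf, 3.85, 3.26, 1.02, 0.73, 1.47, 1.09),
    row("saccade_count",     "metric", 0, Inf, 60.42, 47.87, 17.96, 12.89, 23.58, 16.43),
    row("nasa_tlx",        "scale", 0, 20, 8.974, 5.393, 5.256, 2.290, 6.019, 2.554),
    row("fss",             "scale", 1, 5, 3.804, 0.541, 4.269, 0.633, 2.992, 1.007),
    row("distractibility", "scale", 1, 7, 2.66, 0.94, 2.25, 0.93, 5.45, 1.16),
    row("il",              "scale", 0, 10, 5.76, 2.46, 3.51, 2.30, 4.45, 2.16),
    row("el",              "scale", 0, 10, 1.82, 1.47, 1.34, 1.67, 2.80, 1.89),
    row("gl",              "scale", 0, 10, 6.82, 1.96, 7.66, 2.23, 5.17, 2.65)
  )
}

#' Simulation design specification
#'
#' @param n_participants Number of participants (each completes all
#'   three states).
#' @param series_length Metric time steps per participant-state session.
#' @param sample_rate Gaze sampling rate in Hz.
#' @param seed Master seed; all sub-streams derive from it.
#' @param re_frac Fraction of each measure's total SD assigned to the
#'   additive per-participant random effect (induces the within-subject
#'   correlation a repeated-measures analysis relies on).
#' @param il_coupling Correlation-inducing loading of the intrinsic-load
#'   scale on the session-level metric deviation (0 disables coupling).
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_participants = 26, series_length = 100,
                            sample_rate = 120, seed = 1,
                            re_frac = 0.5, il_coupling = 0.3) {
  stopifnot(n_participants >= 2, series_length >= 2, sample_rate > 0,
            re_frac >= 0, re_frac < 1, abs(il_coupling) < 1)
  structure(list(n_participants = as.integer(n_participants),
                 series_length = as.integer(series_length),
                 sample_rate = sample_rate, seed = as.integer(seed),
                 re_frac = re_frac, il_coupling = il_coupling),
            class = "simulation_spec")
}

# deterministic sub-seed per named random stream
derive_seed <- function(seed, stream) {
  offset <- c(gaze = 1L, metrics = 2L, questionnaires = 3L,
              classifier = 4L, null = 5L)[[stream]]
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

# --- truncated-normal machinery ------------------------------------------

# mean of N(mu, sd) truncated to [lo, up]
truncnorm_mean <- function(mu, sd, lo, up) {
  a <- (lo - mu) / sd; b <- (up - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# latent location whose truncated mean equals `target` (moment matching;
# keeps bounded scales unbiased even when the target sits near a bound)
truncnorm_location <- function(target, sd, lo, up) {
  if (lo == -Inf && up == Inf) return(target)
  stopifnot(target > lo, target < up)
  f <- function(mu) truncnorm_mean(mu, sd, lo, up) - target
  stats::uniroot(f, lower = target - 8 * sd, upper = target + 8 * sd,
                 extendInt = "yes", tol = 1e-10)$root
}

# inverse-CDF truncated-normal draws
rtruncnorm <- function(n, mu, sd, lo, up) {
  pa <- stats::pnorm(lo, mu, sd); pb <- stats::pnorm(up, mu, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mu, sd)
}

# --- gaze-stream simulation ----------------------------------------------

rotate_toward <- function(v, u, deg) {
  # move v along the great circle toward u by `deg` degrees
  ang <- angular_difference(v, u)
  if (ang < 1e-9) return(v)
  d <- min(deg, ang) * pi / 180
  om <- ang * pi / 180
  w <- (sin(om - d) * v + sin(d) * u) / sin(om)
  w / sqrt(sum(w^2))
}

rotate_random <- function(v, deg) {
  # Rodrigues rotation about a random axis perpendicular to v
  r <- stats::rnorm(3)
  axis <- r - sum(r * v) * v
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  w <- v * cos(th) + c(axis[2] * v[3] - axis[3] * v[2],
                       axis[3] * v[1] - axis[1] * v[3],
                       axis[1] * v[2] - axis[2] * v[1]) * sin(th)
  w / sqrt(sum(w^2))
}

#' Default AOI layout for simulated sessions
#'
#' Nine spherical AOIs (the organelles of an animal-cell scene) on a
#' ring 2 m from the viewer, separated by 15 degrees so that saccades
#' between neighbouring AOIs are fast enough to clear the 60 deg/s gate.
#'
#' @return List of [aoi_definition()] objects.
#' @export
default_aoi_layout <- function() {
  organelles <- c("nucleus", "cell_membrane", "cytoplasm",
                  "endoplasmic_reticulum", "ribosome", "golgi_apparatus",
                  "mitochondria", "lysosome", "centrosome")
  lapply(seq_along(organelles), function(i) {
    phi <- (i - 5) * 15 * pi / 180
    aoi_definition(organelles[i], "sphere",
                   center = 2 * c(sin(phi), 0, cos(phi)), size = 0.25)
  })
}

#' Simulate a gaze-direction stream with planted events
#'
#' Produces a 120 Hz (configurable) stream of unit gaze-direction
#' vectors alternating between fixation segments (small angular jitter,
#' velocity below the fixation gate) aimed at AOI centers and saccade
#' segments (great-circle rotation toward the next AOI, velocity above
#' the saccade gate), together with the planted ground-truth event list.
#' With `fix_jitter_v = 0` the stream is noise-free and the I-VT
#' detector recovers the planted events exactly.
#'
#' @param duration_s Session length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @param aois AOI layout (fixation targets); see [default_aoi_layout()].
#' @param fix_jitter_v Within-fixation angular velocity in deg/s
#'   (must stay below the fixation gate).
#' @param sac_v Preferred saccade velocity in deg/s.
#' @param fix_dur_range,sac_dur_range Planted event duration ranges (s),
#'   kept inside the validation windows.
#' @return List with `samples` (tibble `t, dir_x, dir_y, dir_z,
#'   origin_x/y/z`) and `ground_truth` (tibble `kind, t_start, t_end,
#'   i_start, i_end, target`).
#' @export
simulate_gaze_stream <- function(duration_s = 10, sample_rate = 120,
                                 seed = 1, aois = default_aoi_layout(),
                                 fix_jitter_v = 5, sac_v = 300,
                                 fix_dur_range = c(0.120, 0.450),
                                 sac_dur_range = c(0.035, 0.075)) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  stopifnot(duration_s > 0)
  set.seed(seed)
  dt <- 1 / sample_rate
  n_steps <- floor(duration_s * sample_rate)
  centers <- t(vapply(aois, function(a) a$center / sqrt(sum(a$center^2)),
                      numeric(3)))
  target <- sample(nrow(centers), 1)
  dir <- centers[target, ]
  dirs <- matrix(NA_real_, n_steps + 1, 3)
  dirs[1, ] <- dir
  gt <- list()
  step <- 1L
  kind <- "fixation"
  while (TRUE) {
    if (kind == "fixation") {
      len <- round(stats::runif(1, fix_dur_range[1], fix_dur_range[2]) /
                     dt)
    } else {
      nxt <- sample(setdiff(seq_len(nrow(centers)), target), 1)
      amp <- angular_difference(dir, centers[nxt, ])
      len <- max(round(sac_dur_range[1] / dt),
                 min(round(sac_dur_range[2] / dt), round(amp / (sac_v * dt))))
      target <- nxt
    }
    if (step + len - 1 > n_steps) break
    if (kind == "fixation") {
      for (k in seq_len(len)) {
        if (fix_jitter_v > 0) dir <- rotate_random(dir, fix_jitter_v * dt)
        dirs[step + k, ] <- dir
      }
    } else {
      amp <- angular_difference(dir, centers[target, ])
      per <- amp / len  # constant per-step rotation -> constant velocity
      for (k in seq_len(len)) {
        dir <- rotate_toward(dir, centers[target, ], per)
        dirs[step + k, ] <- dir
      }
    }
    gt[[length(gt) + 1]] <- tibble::tibble(
      kind = kind, i_start = step, i_end = step + len,
      t_start = (step - 1) * dt, t_end = (step + len - 1) * dt,
      target = aois[[target]]$aoi_id
    )
    step <- step + len
    kind <- if (kind == "fixation") "saccade" else "fixation"
  }
  n_used <- step
  samples <- tibble::tibble(
    t = (seq_len(n_used) - 1) * dt,
    dir_x = dirs[seq_len(n_used), 1],
    dir_y = dirs[seq_len(n_used), 2],
    dir_z = dirs[seq_len(n_used), 3],
    origin_x = 0, origin_y = 0, origin_z = 0
  )
  list(samples = samples, ground_truth = dplyr::bind_rows(gt))
}

# --- metric dataset -------------------------------------------------------

draw_session_aggregates <- function(spec, targets) {
  # per participant x state x measure aggregate draws with an additive
  # participant random effect; truncated-normal locations moment-matched
  sd_b <- spec$re_frac
  sd_w <- sqrt(1 - spec$re_frac^2)
  draws <- list()
  for (m in unique(targets$measure)) {
    tm <- targets[targets$measure == m, ]
    # one participant effect per measure, on the printed-SD scale
    b <- stats::rnorm(spec$n_participants, 0, sd_b)
    for (s in seq_len(nrow(tm))) {
      mu0 <- truncnorm_location(tm$mean[s], tm$sd[s], tm$lower[s], tm$upper[s])
      eps <- stats::runif(spec$n_participants)
      mu_i <- mu0 + b * tm$sd[s]
      pa <- stats::pnorm(tm$lower[s], mu_i, sd_w * tm$sd[s])
      pb <- stats::pnorm(tm$upper[s], mu_i, sd_w * tm$sd[s])
      val <- stats::qnorm(pa + eps * (pb - pa), mu_i, sd_w * tm$sd[s])
      draws[[length(draws) + 1]] <- tibble::tibble(
        participant_id = sprintf("P%02d", seq_len(spec$n_participants)),
        state = tm$state[s],
        state_label = state_levels[[tm$state[s]]],
        measure = m, value = val
      )
    }
  }
  dplyr::bind_rows(draws)
}

cumulative_path <- function(count, total_duration, L) {
  # monotone cumulative metric path: `count` events at uniform positions,
  # random positive duration shares summing to the session aggregate
  count <- max(1L, as.integer(round(count)))
  pos <- sort(sample.int(L, count, replace = TRUE))
  counts <- cumsum(tabulate(pos, L))
  w <- stats::runif(count)
  w <- w / sum(w) * total_duration
  inc <- numeric(L)
  for (i in seq_len(count)) inc[pos[i]] <- inc[pos[i]] + w[i]
  list(count = counts, duration = cumsum(inc))
}

#' Simulate the full per-session metric dataset
#'
#' Generates, for every participant and state, a monotone cumulative
#' metric time series of `series_length` steps whose final aggregates
#' are drawn around the calibration targets with an additive
#' per-participant random effect. With the defaults this yields
#' 26 x 3 = 78 sessions and 7800 labelled time steps (2600 per class).
#'
#' @param spec A [simulation_spec()].
#' @param targets Calibration table; defaults to [reference_targets()]
#'   metrics.
#' @return List with `series` (long tibble: `participant_id`,
#'   `state`, `state_label`, `step`, `t`, four cumulative metric
#'   columns) and `aggregates` (final per-session values, long form).
#' @export
simulate_metric_dataset <- function(spec = simulation_spec(),
                                    targets = NULL) {
  if (is.null(targets)) {
    targets <- reference_targets()
    targets <- targets[targets$kind == "metric", ]
  }
  set.seed(derive_seed(spec$seed, "metrics"))
  agg <- draw_session_aggregates(spec, targets)
  L <- spec$series_length
  wide <- tidyr::pivot_wider(agg, names_from = "measure",
                             values_from = "value")
  rows <- lapply(seq_len(nrow(wide)), function(i) {
    fx <- cumulative_path(wide$fixation_count[i], wide$fixation_duration[i], L)
    sc <- cumulative_path(wide$saccade_count[i], wide$saccade_duration[i], L)
    tibble::tibble(
      participant_id = wide$participant_id[i],
      state = wide$state[i], state_label = wide$state_label[i],
      step = seq_len(L), t = (seq_len(L) - 1) / 10,
      fixation_duration = fx$duration, fixation_count = fx$count,
      saccade_duration = sc$duration, saccade_count = sc$count
    )
  })
  series <- dplyr::bind_rows(rows)
  # integerize the stored count aggregates to match the emitted paths
  agg$value[agg$measure %in% c("fixation_count", "saccade_count")] <-
    pmax(1, round(agg$value[agg$measure %in% c("fixation_count",
                                               "saccade_count")]))
  list(series = series, aggregates = agg)
}

#' Simulate questionnaire scale scores
#'
#' Truncated-normal draws per scale and state around the calibration
#' targets, with the same per-participant random-effect structure as the
#' metric aggregates. When `metric_z` is supplied (a per-session
#' standardized metric deviation), the intrinsic-load scale loads on it
#' with weight `spec$il_coupling`, inducing the positive IL-metric
#' correlations seen in pooled session-level analyses.
#'
#' @param spec A [simulation_spec()].
#' @param targets Calibration table; defaults to [reference_targets()]
#'   scales.
#' @param metric_z Optional tibble `participant_id, state, z` of
#'   session-level standardized metric deviations.
#' @return Long tibble `participant_id, state, state_label, measure,
#'   value`.
#' @export
simulate_questionnaires <- function(spec = simulation_spec(),
                                    targets = NULL, metric_z = NULL) {
  if (is.null(targets)) {
    targets <- reference_targets()
    targets <- targets[targets$kind == "scale", ]
  }
  set.seed(derive_seed(spec$seed, "questionnaires"))
  sd_b <- spec$re_frac
  sd_w <- sqrt(1 - spec$re_frac^2)
  n <- spec$n_participants
  pid <- sprintf("P%02d", seq_len(n))
  out <- list()
  for (m in unique(targets$measure)) {
    tm <- targets[targets$measure == m, ]
    b <- stats::rnorm(n, 0, sd_b)
    rho <- if (m == "il" && !is.null(metric_z)) spec$il_coupling else 0
    for (s in seq_len(nrow(tm))) {
      mu0 <- truncnorm_location(tm$mean[s], tm$sd[s], tm$lower[s], tm$upper[s])
      z <- if (rho != 0) {
        mz <- metric_z[metric_z$state == tm$state[s], ]
        mz$z[match(pid, mz$participant_id)]
      } else rep(0, n)
      mu_i <- mu0 + (b + sd_w * rho * z) * tm$sd[s]
      sdw <- sd_w * sqrt(1 - rho^2) * tm$sd[s]
      eps <- stats::runif(n)
      pa <- stats::pnorm(tm$lower[s], mu_i, sdw)
      pb <- stats::pnorm(tm$upper[s], mu_i, sdw)
      val <- stats::qnorm(pa + eps * (pb - pa), mu_i, sdw)
      out[[length(out) + 1]] <- tibble::tibble(
        participant_id = pid, state = tm$state[s],
        state_label = state_levels[[tm$state[s]]],
        measure = m, value = val
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate the complete study dataset
#'
#' Convenience wrapper producing the metric dataset and the coupled
#' questionnaire scores from one specification and seed.
#'
#' @param spec A [simulation_spec()].
#' @return List with `series`, `aggregates`, `questionnaires` and the
#'   `spec` used.
#' @export
simulate_study <- function(spec = simulation_spec()) {
  met <- simulate_metric_dataset(spec)
  targets <- reference_targets()
  tm <- targets[targets$kind == "metric", ]
  z <- met$aggregates |>
    dplyr::left_join(tm[, c("measure", "state", "mean", "sd")],
                     by = c("measure", "state")) |>
    dplyr::mutate(zi = (.data$value - .data$mean) / .data$sd) |>
    dplyr::group_by(.data$participant_id, .data$state) |>
    dplyr::summarise(z = mean(.data$zi), .groups = "drop")
  quest <- simulate_questionnaires(spec, metric_z = z)
  list(series = met$series, aggregates = met$aggregates,
       questionnaires = quest, spec = spec)
}

#' Score a multi-item questionnaire
#'
#' Reflected (reverse-keyed) items are recoded as
#' `scale_max + scale_min - response`; the scale score is the mean of
#' the coded items.
#'
#' @param responses Numeric item responses.
#' @param scale_min,scale_max Item response bounds.
#' @param reflected Logical vector marking reverse-keyed items
#'   (recycled if length 1).
#' @return Scale score (mean of coded items).
#' @export
score_questionnaire <- function(responses, scale_min, scale_max,
                                reflected = FALSE) {
  reflected <- rep_len(reflected, length(responses))
  if (any(responses < scale_min | responses > scale_max)) {
    stop("response outside the item scale bounds [",
         scale_min, ", ", scale_max, "]")
  }
  coded <- ifelse(reflected, scale_max + scale_min - responses, responses)
  mean(coded)
}
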