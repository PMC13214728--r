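#' Detection thresholds for fixations and saccades
#'
#' Builds the threshold configuration used by the I-VT detector. The
#' defaults are the standard HMD eye-tracking gates: a sample pair is a
#' fixation candidate below 30 deg/s and a saccade candidate above
#' 60 deg/s, and candidate events are kept only when their duration falls
#' in the kind-specific window (fixations 100-500 ms, saccades 30-80 ms).
#'
#' @param v_fix_max Maximum angular velocity (deg/s) for a fixation pair.
#' @param v_sac_min Minimum angular velocity (deg/s) for a saccade pair.
#' @param fix_dur_min,fix_dur_max Fixation duration window, seconds.
#' @param sac_dur_min,sac_dur_max Saccade duration window, seconds.
#' @return A list of class `"threshold_config"`.
#' @export
threshold_config <- function(v_fix_max = 30, v_sac_min = 60,
                             fix_dur_min = 0.100, fix_dur_max = 0.500,
                             sac_dur_min = 0.030, sac_dur_max = 0.080) {
  stopifnot(v_fix_max > 0, v_sac_min >= v_fix_max,
            fix_dur_min > 0, fix_dur_max > fix_dur_min,
            sac_dur_min > 0, sac_dur_max > sac_dur_min)
  structure(list(v_fix_max = v_fix_max, v_sac_min = v_sac_min,
                 fix_dur_min = fix_dur_min, fix_dur_max = fix_dur_max,
                 sac_dur_min = sac_dur_min, sac_dur_max = sac_dur_max),
            class = "threshold_config")
}

normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(!is.finite(nrm)) || any(nrm == 0)) {
    stop("gaze direction vectors must be finite and nonzero")
  }
  m / nrm
}

#' Angular difference between two gaze directions
#'
#' Angle between two 3D direction vectors, in degrees. Inputs are
#' renormalized defensively; the dot product is clamped to \[-1, 1\]
#' before `acos` so collinear vectors never produce NaN.
#'
#' @param v1,v2 Numeric length-3 direction vectors (need not be unit).
#' @return Angle in degrees, in \[0, 180\].
#' @export
angular_difference <- function(v1, v2) {
  stopifnot(length(v1) == 3, length(v2) == 3)
  m <- normalize_rows(rbind(as.numeric(v1), as.numeric(v2)))
  d <- min(1, max(-1, sum(m[1, ] * m[2, ])))
  acos(d) * 180 / pi
}

#' Angular gaze velocity
#'
#' v = dtheta / dt, the I-VT velocity of one consecutive sample pair.
#'
#' @param dtheta Angular difference in degrees.
#' @param dt Inter-sample interval in seconds; must be positive.
#' @return Velocity in degrees per second.
#' @export
gaze_velocity <- function(dtheta, dt) {
  if (any(dt <= 0)) stop("inter-sample interval dt must be positive")
  dtheta / dt
}

#' Per-pair angular velocities of a gaze stream
#'
#' @param samples Data frame with columns `t`, `dir_x`, `dir_y`, `dir_z`
#'   (timestamps strictly increasing, directions normalized on entry).
#' @return Tibble with one row per consecutive pair: `t` (time of the
#'   later sample), `dtheta` (deg), `dt` (s), `v` (deg/s).
#' @export
gaze_velocities <- function(samples) {
  stopifnot(nrow(samples) >= 2)
  t <- samples$t
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  dirs <- normalize_rows(as.matrix(samples[, c("dir_x", "dir_y", "dir_z")]))
  n <- nrow(dirs)
  dots <- rowSums(dirs[-n, , drop = FALSE] * dirs[-1, , drop = FALSE])
  dots <- pmin(1, pmax(-1, dots))
  dtheta <- acos(dots) * 180 / pi
  dt <- diff(t)
  tibble::tibble(t = t[-1], dtheta = dtheta, dt = dt,
                 v = gaze_velocity(dtheta, dt))
}

#' Classify sample pairs as fixation, saccade or unclassified
#'
#' A pair is `"fixation"` iff v < `v_fix_max`, `"saccade"` iff
#' v > `v_sac_min`, otherwise `"unclassified"` (velocities in the gap
#' between the two thresholds carry no label and terminate event runs).
#'
#' @param samples Gaze sample data frame (see [gaze_velocities()]).
#' @param cfg A [threshold_config()].
#' @return Character vector, one label per consecutive sample pair.
#' @export
classify_samples <- function(samples, cfg = threshold_config()) {
  vel <- gaze_velocities(samples)
  labels <- rep("unclassified", nrow(vel))
  labels[vel$v < cfg$v_fix_max] <- "fixation"
  labels[vel$v > cfg$v_sac_min] <- "saccade"
  labels
}

#' Group labelled sample pairs into candidate events
#'
#' Maximal contiguous runs of identical non-unclassified labels become
#' candidate events. Unclassified pairs, and gaps longer than
#' `gap_factor` times the median inter-sample interval (dropped frames,
#' blinks), terminate any open run.
#'
#' @param labels Character labels, one per sample pair.
#' @param times Sample timestamps (length = length(labels) + 1); pair i
#'   spans `times[i]` to `times[i + 1]`.
#' @param gap_factor Multiple of the median interval above which a pair
#'   is treated as a recording gap.
#' @return Tibble of candidates: `kind`, `t_start`, `t_end`, `duration`,
#'   `i_start`, `i_end` (sample indices).
#' @export
segment_events <- function(labels, times, gap_factor = 3) {
  stopifnot(length(times) == length(labels) + 1)
  if (length(labels) == 0) {
    return(tibble::tibble(kind = character(), t_start = numeric(),
                          t_end = numeric(), duration = numeric(),
                          i_start = integer(), i_end = integer()))
  }
  dt <- diff(times)
  gap <- dt > gap_factor * stats::median(dt)
  eff <- ifelse(gap, "gap", labels)
  runs <- rle(eff)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values %in% c("fixation", "saccade")
  t_start <- times[starts[keep]]
  t_end <- times[ends[keep] + 1]
  tibble::tibble(
    kind = runs$values[keep],
    t_start = t_start,
    t_end = t_end,
    duration = t_end - t_start,
    i_start = as.integer(starts[keep]),
    i_end = as.integer(ends[keep] + 1)
  )
}

#' Duration-validate candidate events
#'
#' Keeps only candidates whose duration lies inside the kind-specific
#' window (fixation 100-500 ms, saccade 30-80 ms by default). Candidates
#' outside the window are discarded entirely, not truncated: duration is
#' a validity gate, not a segmentation rule.
#'
#' @param raw Candidate events from [segment_events()].
#' @param cfg A [threshold_config()].
#' @return The validated subset, order preserved.
#' @export
validate_events <- function(raw, cfg = threshold_config()) {
  ok <- ifelse(
    raw$kind == "fixation",
    raw$duration >= cfg$fix_dur_min & raw$duration <= cfg$fix_dur_max,
    raw$duration >= cfg$sac_dur_min & raw$duration <= cfg$sac_dur_max
  )
  raw[ok, , drop = FALSE]
}

#' I-VT fixation/saccade detection
#'
#' End-to-end velocity-threshold identification: per-pair angular
#' velocity from consecutive gaze-direction vectors, thresholding into
#' fixation/saccade/unclassified pairs, run-length grouping, and
#' duration validation. The mean gaze direction of each event's samples
#' is attached (renormalized arithmetic mean).
#'
#' @param samples Gaze sample data frame with columns
#'   `t, dir_x, dir_y, dir_z` and optionally `origin_x, origin_y,
#'   origin_z`.
#' @param cfg A [threshold_config()].
#' @return Tibble of validated gaze events with columns `kind`,
#'   `t_start`, `t_end`, `duration`, `i_start`, `i_end`, `mean_dir_x/y/z`.
#' @export
detect_gaze_events <- function(samples, cfg = threshold_config()) {
  labels <- classify_samples(samples, cfg)
  ev <- validate_events(segment_events(labels, samples$t), cfg)
  dirs <- normalize_rows(as.matrix(samples[, c("dir_x", "dir_y", "dir_z")]))
  md <- t(vapply(seq_len(nrow(ev)), function(i) {
    m <- colMeans(dirs[ev$i_start[i]:ev$i_end[i], , drop = FALSE])
    m / sqrt(sum(m^2))
  }, numeric(3)))
  if (nrow(ev) == 0) md <- matrix(numeric(), 0, 3)
  ev$mean_dir_x <- md[, 1]
  ev$mean_dir_y <- md[, 2]
  ev$mean_dir_z <- md[, 3]
  ev
}

#' Read / write gaze-sample CSV
#'
#' Column layout: `timestamp_s,dir_x,dir_y,dir_z[,origin_x,origin_y,origin_z]`.
#' Scene units are meters in a right-handed coordinate system.
#'
#' @param path File path.
#' @return `read_gaze_csv()` returns a tibble with columns `t`,
#'   `dir_x/y/z` and, when present, `origin_x/y/z`.
#' @export
read_gaze_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("timestamp_s", "dir_x", "dir_y", "dir_z")
  if (!all(need %in% names(x))) {
    stop("gaze CSV must have columns ", paste(need, collapse = ", "))
  }
  dplyr::rename(x, t = "timestamp_s")
}

#' @param samples Gaze sample tibble as returned by [read_gaze_csv()].
#' @rdname read_gaze_csv
#' @export
write_gaze_csv <- function(samples, path) {
  out <- dplyr::rename(samples, timestamp_s = "t")
  readr::write_csv(out, path)
  invisible(path)
}

#' Write detected events to CSV
#'
#' Durations are exported in milliseconds to match the printed units of
#' the detection thresholds; timestamps stay in seconds.
#'
#' @param events Events from [detect_gaze_events()].
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  out <- tibble::tibble(kind = events$kind,
                        t_start_s = events$t_start,
                        t_end_s = events$t_end,
                        duration_ms = events$duration * 1000)
  readr::write_csv(out, path)
  invisible(path)
}
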