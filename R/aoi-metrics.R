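#' Define an area of interest
#'
#' An AOI is a named scene region — here typically an organelle model —
#' represented as a sphere or an axis-aligned box in meters.
#'
#' @param aoi_id Unique label.
#' @param shape `"sphere"` or `"box"`.
#' @param center Numeric length-3 center position.
#' @param size Radius (sphere) or length-3 half-extents (box); all > 0.
#' @return A list of class `"aoi"`.
#' @export
aoi_definition <- function(aoi_id, shape = c("sphere", "box"),
                           center, size) {
  shape <- match.arg(shape)
  center <- as.numeric(center)
  size <- as.numeric(size)
  stopifnot(length(center) == 3)
  if (shape == "sphere" && (length(size) != 1 || size <= 0)) {
    stop("sphere AOI needs a single positive radius")
  }
  if (shape == "box" && (length(size) != 3 || any(size <= 0))) {
    stop("box AOI needs three positive half-extents")
  }
  structure(list(aoi_id = aoi_id, shape = shape,
                 center = center, size = size), class = "aoi")
}

#' Read AOI definitions from JSON
#'
#' Expected layout: an array of objects with fields `aoi_id`, `shape`,
#' `center` and `radius` (spheres) or `half_extents` (boxes).
#'
#' @param path JSON file path.
#' @return List of [aoi_definition()] objects.
#' @export
read_aoi_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  aois <- lapply(raw, function(a) {
    aoi_definition(a$aoi_id, a$shape, unlist(a$center),
                   if (a$shape == "sphere") a$radius else unlist(a$half_extents))
  })
  ids <- vapply(aois, `[[`, "", "aoi_id")
  if (anyDuplicated(ids)) stop("duplicate aoi_id in ", path)
  aois
}

#' @rdname read_aoi_json
#' @param aois List of AOI definitions.
#' @export
write_aoi_json <- function(aois, path) {
  out <- lapply(aois, function(a) {
    b <- list(aoi_id = a$aoi_id, shape = a$shape, center = a$center)
    if (a$shape == "sphere") b$radius <- a$size else b$half_extents <- a$size
    b
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ray / AOI intersection
#'
#' Sphere test via the quadratic discriminant, box test via the slab
#' method. The nearest non-negative entry distance is reported; a ray
#' starting inside the volume hits at distance 0.
#'
#' @param origin Ray origin, length-3.
#' @param dir Unit direction, length-3.
#' @param aoi An [aoi_definition()].
#' @return List with `hit` (logical) and `distance` (NA when no hit).
#' @export
ray_aoi_intersect <- function(origin, dir, aoi) {
  origin <- as.numeric(origin); dir <- as.numeric(dir)
  dir <- dir / sqrt(sum(dir^2))
  if (aoi$shape == "sphere") {
    oc <- origin - aoi$center
    b <- sum(oc * dir)
    c0 <- sum(oc^2) - aoi$size^2
    disc <- b^2 - c0
    if (disc < 0) return(list(hit = FALSE, distance = NA_real_))
    s <- sqrt(disc)
    t1 <- -b - s; t2 <- -b + s
    tt <- if (t1 >= 0) t1 else if (t2 >= 0) max(t1, 0) else NA_real_
    if (is.na(tt)) return(list(hit = FALSE, distance = NA_real_))
    return(list(hit = TRUE, distance = tt))
  }
  # axis-aligned box: slab intersection per axis
  lo <- aoi$center - aoi$size
  hi <- aoi$center + aoi$size
  tmin <- -Inf; tmax <- Inf
  for (k in 1:3) {
    if (dir[k] == 0) {
      if (origin[k] < lo[k] || origin[k] > hi[k]) {
        return(list(hit = FALSE, distance = NA_real_))
      }
    } else {
      ta <- (lo[k] - origin[k]) / dir[k]
      tb <- (hi[k] - origin[k]) / dir[k]
      tmin <- max(tmin, min(ta, tb))
      tmax <- min(tmax, max(ta, tb))
    }
  }
  if (tmax < tmin || tmax < 0) return(list(hit = FALSE, distance = NA_real_))
  list(hit = TRUE, distance = max(tmin, 0))
}

first_hit_aoi <- function(origin, dir, aois) {
  best <- NA_character_; bestd <- Inf
  for (a in aois) {
    h <- ray_aoi_intersect(origin, dir, a)
    if (h$hit && h$distance < bestd) {
      bestd <- h$distance
      best <- a$aoi_id
    }
  }
  best
}

#' Attribute gaze events to AOIs
#'
#' Each event is attributed to the AOI hit by the majority of its
#' samples' gaze rays (nearest AOI per ray), or to `"none"` when no
#' sample ray hits anything. Ties are broken in favour of the AOI hit
#' earliest within the event.
#'
#' @param events Validated events from [detect_gaze_events()].
#' @param samples The gaze samples the events index into; rows may carry
#'   `origin_x/y/z` (default origin is the scene origin).
#' @param aois List of [aoi_definition()] objects.
#' @return `events` with an `aoi_id` column appended.
#' @export
attribute_events <- function(events, samples, aois) {
  has_origin <- all(c("origin_x", "origin_y", "origin_z") %in% names(samples))
  dirs <- normalize_rows(as.matrix(samples[, c("dir_x", "dir_y", "dir_z")]))
  aoi_id <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    idx <- events$i_start[i]:events$i_end[i]
    hits <- vapply(idx, function(j) {
      o <- if (has_origin) {
        c(samples$origin_x[j], samples$origin_y[j], samples$origin_z[j])
      } else c(0, 0, 0)
      h <- first_hit_aoi(o, dirs[j, ], aois)
      if (is.na(h)) "" else h
    }, "")
    hits <- hits[hits != ""]
    if (length(hits) == 0) {
      aoi_id[i] <- "none"
    } else {
      tab <- table(hits)
      winners <- names(tab)[tab == max(tab)]
      # earliest-hit tie break
      aoi_id[i] <- hits[hits %in% winners][1]
    }
  }
  events$aoi_id <- aoi_id
  events
}

#' Accumulate cumulative eye-tracking metrics per AOI
#'
#' Emits one record per clock tick per AOI carrying the four cumulative
#' metrics (fixation duration/count, saccade duration/count). Each
#' completed event adds its full duration and increments the matching
#' count by one at its end time; metrics are therefore non-decreasing.
#'
#' @param events Attributed events (with `aoi_id`).
#' @param clock Emission time grid in seconds (e.g. `seq(0, 10, by = 0.1)`
#'   for a 10 Hz recording of a 10 s session).
#' @param aoi_ids AOIs to report; defaults to those seen in `events`
#'   (excluding `"none"`).
#' @return Tibble with columns `t, aoi_id, fixation_duration,
#'   fixation_count, saccade_duration, saccade_count`.
#' @export
accumulate_metrics <- function(events, clock,
                               aoi_ids = setdiff(unique(events$aoi_id), "none")) {
  if (length(aoi_ids) == 0) aoi_ids <- "none"
  out <- lapply(aoi_ids, function(id) {
    ev <- events[events$aoi_id == id & events$aoi_id != "none", , drop = FALSE]
    fx <- ev[ev$kind == "fixation", , drop = FALSE]
    sc <- ev[ev$kind == "saccade", , drop = FALSE]
    cum_at <- function(e, field) {
      vapply(clock, function(tt) {
        done <- e$t_end <= tt
        if (field == "count") sum(done) else sum(e$duration[done])
      }, 0)
    }
    tibble::tibble(
      t = clock, aoi_id = id,
      fixation_duration = cum_at(fx, "duration"),
      fixation_count = as.integer(cum_at(fx, "count")),
      saccade_duration = cum_at(sc, "duration"),
      saccade_count = as.integer(cum_at(sc, "count"))
    )
  })
  dplyr::bind_rows(out)
}

metric_csv_cols <- c("timestamp_s", "aoi_id", "fixation_duration_s",
                     "fixation_count", "saccade_duration_s", "saccade_count")

#' Read / write metric time-series CSV
#'
#' Column layout:
#' `timestamp_s,aoi_id,fixation_duration_s,fixation_count,saccade_duration_s,saccade_count`.
#' Numeric values round-trip at 6 decimals.
#'
#' @param series Metric tibble from [accumulate_metrics()].
#' @param path File path.
#' @export
write_metrics_csv <- function(series, path) {
  out <- tibble::tibble(
    timestamp_s = round(series$t, 6),
    aoi_id = series$aoi_id,
    fixation_duration_s = round(series$fixation_duration, 6),
    fixation_count = series$fixation_count,
    saccade_duration_s = round(series$saccade_duration, 6),
    saccade_count = series$saccade_count
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(aoi_id = readr::col_character()))
  missing <- setdiff(metric_csv_cols, names(x))
  if (length(missing) > 0) {
    stop("metrics CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(is.na(x$timestamp_s))
  if (length(bad) > 0) {
    stop("metrics CSV ", path, ": unparseable row at line ", bad[1] + 1)
  }
  tibble::tibble(
    t = x$timestamp_s, aoi_id = x$aoi_id,
    fixation_duration = x$fixation_duration_s,
    fixation_count = as.integer(x$fixation_count),
    saccade_duration = x$saccade_duration_s,
    saccade_count = as.integer(x$saccade_count)
  )
}
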