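test_that("ray-sphere intersection covers head-on, miss and tangent cases", {
  a <- aoi_definition("s", "sphere", center = c(0, 0, 5), size = 1)
  head_on <- ray_aoi_intersect(c(0, 0, 0), c(0, 0, 1), a)
  expect_true(head_on$hit)
  expect_equal(head_on$distance, 4)
  expect_false(ray_aoi_intersect(c(0, 0, 0), c(0, 0, -1), a)$hit)
  # tangent ray: discriminant exactly zero, grazes at the sphere's side
  tang <- ray_aoi_intersect(c(1, 0, 0), c(0, 0, 1), a)
  expect_true(tang$hit)
  expect_equal(tang$distance, 5)
  # ray starting inside hits at distance zero
  inside <- ray_aoi_intersect(c(0, 0, 5), c(1, 0, 0), a)
  expect_true(inside$hit)
  expect_equal(inside$distance, 0)
  expect_error(aoi_definition("bad", "sphere", c(0, 0, 0), -1), "radius")
})

test_that("ray-box slab test handles hits, misses and axis-parallel rays", {
  b <- aoi_definition("b", "box", center = c(0, 0, 5), size = c(1, 1, 1))
  h <- ray_aoi_intersect(c(0, 0, 0), c(0, 0, 1), b)
  expect_true(h$hit)
  expect_equal(h$distance, 4)
  expect_false(ray_aoi_intersect(c(3, 0, 0), c(0, 0, 1), b)$hit)
  diag_hit <- ray_aoi_intersect(c(-2, 0, 3), c(1, 0, 1) / sqrt(2), b)
  expect_true(diag_hit$hit)
})

test_that("geometry agrees with a dense point-sampling oracle", {
  set.seed(21)
  for (i in 1:200) {
    a <- aoi_definition("s", "sphere", center = stats::rnorm(3, sd = 3),
                        size = stats::runif(1, 0.3, 2))
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    got <- ray_aoi_intersect(c(0, 0, 0), dir, a)
    ts <- seq(0, 12, by = 0.005)
    pts <- outer(ts, dir)
    inside <- sqrt(rowSums(sweep(pts, 2, a$center)^2)) <= a$size
    expect_equal(got$hit, any(inside))
    if (got$hit && any(inside)) {
      expect_equal(got$distance, ts[which(inside)[1]], tolerance = 0.01)
    }
  }
})

test_that("events are attributed to the majority AOI with earliest-hit ties", {
  aois <- list(aoi_definition("left", "sphere", c(-1, 0, 4), 0.8),
               aoi_definition("right", "sphere", c(1, 0, 4), 0.8))
  # 5 samples: 3 rays at left, 2 at right -> majority left
  dirs <- rbind(c(-1, 0, 4), c(-1, 0, 4), c(-1, 0, 4),
                c(1, 0, 4), c(1, 0, 4))
  samples <- tibble::tibble(t = (0:4) / 120,
                            dir_x = dirs[, 1], dir_y = dirs[, 2],
                            dir_z = dirs[, 3])
  ev <- tibble::tibble(kind = "fixation", t_start = 0, t_end = 4 / 120,
                       duration = 4 / 120, i_start = 1L, i_end = 5L)
  expect_equal(attribute_events(ev, samples, aois)$aoi_id, "left")
  # 2-2 split with right seen first -> tie broken by earliest hit
  samples2 <- samples[c(4, 5, 1, 2), ]
  ev2 <- tibble::tibble(kind = "fixation", t_start = 0, t_end = 3 / 120,
                        duration = 3 / 120, i_start = 1L, i_end = 4L)
  expect_equal(attribute_events(ev2, samples2, aois)$aoi_id, "right")
  # no hits -> none
  samples3 <- tibble::tibble(t = 0:1 / 120, dir_x = 0, dir_y = 1, dir_z = 0)
  ev3 <- tibble::tibble(kind = "fixation", t_start = 0, t_end = 1 / 120,
                        duration = 1 / 120, i_start = 1L, i_end = 2L)
  expect_equal(attribute_events(ev3, samples3, aois)$aoi_id, "none")
})

test_that("metric accumulation is additive, monotone and conserves counts", {
  ev <- tibble::tibble(
    kind = c("fixation", "fixation", "saccade"),
    t_start = c(0.1, 0.5, 0.9), t_end = c(0.3, 0.8, 0.95),
    duration = c(0.2, 0.3, 0.05), i_start = 1L, i_end = 2L,
    aoi_id = "nucleus"
  )
  met <- accumulate_metrics(ev, clock = seq(0, 1, by = 0.1))
  last <- met[nrow(met), ]
  expect_equal(last$fixation_duration, 0.5)
  expect_equal(last$fixation_count, 2L)
  expect_equal(last$saccade_duration, 0.05)
  expect_equal(last$saccade_count, 1L)
  for (col in c("fixation_duration", "fixation_count",
                "saccade_duration", "saccade_count")) {
    expect_true(all(diff(met[[col]]) >= 0))
  }
  # no events -> all-zero series
  none <- accumulate_metrics(ev[0, ], clock = seq(0, 1, by = 0.5))
  expect_true(all(none$fixation_count == 0))
})

test_that("total attributed fixation counts are conserved across AOIs", {
  gs <- simulate_gaze_stream(duration_s = 6, seed = 13, fix_jitter_v = 0)
  ev <- attribute_events(detect_gaze_events(gs$samples), gs$samples,
                         default_aoi_layout())
  met <- accumulate_metrics(ev, clock = max(gs$samples$t))
  n_attr <- sum(ev$kind == "fixation" & ev$aoi_id != "none")
  expect_equal(sum(met$fixation_count), n_attr)
})

test_that("metric CSV round-trips and rejects malformed files", {
  ev <- tibble::tibble(kind = "fixation", t_start = 0.1, t_end = 0.3,
                       duration = 0.2, i_start = 1L, i_end = 2L,
                       aoi_id = "nucleus")
  met <- accumulate_metrics(ev, clock = c(0, 0.5, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(met, f)
  back <- read_metrics_csv(f)
  expect_equal(back, met, tolerance = 1e-6)
  # header-only file -> empty series
  writeLines(paste(c("timestamp_s", "aoi_id", "fixation_duration_s",
                     "fixation_count", "saccade_duration_s",
                     "saccade_count"), collapse = ","), f)
  expect_equal(nrow(read_metrics_csv(f)), 0)
  # missing column -> parse error
  writeLines(c("timestamp_s,aoi_id", "0,nucleus"), f)
  expect_error(read_metrics_csv(f), "missing column")
})

test_that("AOI JSON definitions round-trip", {
  aois <- default_aoi_layout()
  f <- withr::local_tempfile(fileext = ".json")
  write_aoi_json(aois, f)
  back <- read_aoi_json(f)
  expect_equal(length(back), length(aois))
  expect_equal(back[[1]]$center, aois[[1]]$center)
  expect_equal(back[[1]]$aoi_id, aois[[1]]$aoi_id)
})
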