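#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (detection thresholds, simulation spec, classifier
#' hyperparameters) and aggregates human-readable contradiction errors
#' (e.g. fixation gate above saccade gate, window longer than the
#' series).
#'
#' @param config Named list; recognized entries are `thresholds`
#'   (list of [threshold_config()] arguments), `sim` (list of
#'   [simulation_spec()] arguments), `hp` (list of [hyperparams()]
#'   arguments) and `seed`.
#' @return Normalized config list with `thresholds`, `sim`, `hp`,
#'   `seed`; errors (all of them, collected) if the config is
#'   contradictory.
#' @export
validate_config <- function(config = list()) {
  errors <- character()
  seed <- config$seed %||% 1L
  thr <- tryCatch(do.call(threshold_config, config$thresholds %||% list()),
                  error = function(e) {
                    errors <<- c(errors, conditionMessage(e)); NULL
                  })
  sim_args <- config$sim %||% list()
  sim_args$seed <- sim_args$seed %||% seed
  sim <- tryCatch(do.call(simulation_spec, sim_args),
                  error = function(e) {
                    errors <<- c(errors, conditionMessage(e)); NULL
                  })
  hp_args <- config$hp %||% list()
  hp_args$seed <- hp_args$seed %||% derive_seed(seed, "classifier")
  hp <- tryCatch(do.call(hyperparams, hp_args),
                 error = function(e) {
                   errors <<- c(errors, conditionMessage(e)); NULL
                 })
  if (!is.null(thr) && thr$v_fix_max > thr$v_sac_min) {
    errors <- c(errors, "v_fix_max exceeds v_sac_min")
  }
  if (!is.null(sim) && !is.null(hp) &&
      hp$window_length > sim$series_length) {
    errors <- c(errors,
                sprintf("window length %d exceeds series length %d",
                        hp$window_length, sim$series_length))
  }
  if (length(errors) > 0) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  list(thresholds = thr, sim = sim, hp = hp, seed = as.integer(seed))
}

#' Run the full analysis pipeline
#'
#' Simulate -> detect -> accumulate metrics -> statistics -> classify,
#' writing each stage's outputs and a reproducibility manifest (config,
#' seed, output checksums) under `out_dir`. Stages can be skipped; a
#' stage failure aborts with a stage-named error, retaining the outputs
#' written so far.
#'
#' @param config Config list (see [validate_config()]).
#' @param out_dir Output directory (created if needed).
#' @param stages Which stages to run.
#' @param classify_model Classifier for the classify stage.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir,
                         stages = c("simulate", "detect", "metrics",
                                    "stats", "classify"),
                         classify_model = "lstm") {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  study <- NULL
  if ("simulate" %in% stages) {
    study <- run_stage("simulate", function() {
      st <- simulate_study(cfg$sim)
      readr::write_csv(st$series, file.path(out_dir, "series.csv"))
      readr::write_csv(st$aggregates, file.path(out_dir, "aggregates.csv"))
      readr::write_csv(st$questionnaires,
                       file.path(out_dir, "questionnaires.csv"))
      st
    })
    outputs <- c(outputs, file.path(out_dir, c(
      "series.csv", "aggregates.csv", "questionnaires.csv")))
  }
  if ("detect" %in% stages) {
    run_stage("detect", function() {
      gs <- simulate_gaze_stream(duration_s = 10,
                                 sample_rate = cfg$sim$sample_rate,
                                 seed = derive_seed(cfg$seed, "gaze"))
      write_gaze_csv(gs$samples, file.path(out_dir, "gaze_example.csv"))
      ev <- detect_gaze_events(gs$samples, cfg$thresholds)
      write_events_csv(ev, file.path(out_dir, "events_example.csv"))
      ev
    })
    outputs <- c(outputs, file.path(out_dir, c(
      "gaze_example.csv", "events_example.csv")))
  }
  if ("metrics" %in% stages) {
    run_stage("metrics", function() {
      gs <- simulate_gaze_stream(duration_s = 10,
                                 sample_rate = cfg$sim$sample_rate,
                                 seed = derive_seed(cfg$seed, "gaze"))
      ev <- detect_gaze_events(gs$samples, cfg$thresholds)
      ev <- attribute_events(ev, gs$samples, default_aoi_layout())
      met <- accumulate_metrics(ev, clock = seq(0, 10, by = 0.1))
      write_metrics_csv(met, file.path(out_dir, "metrics_example.csv"))
      met
    })
    outputs <- c(outputs, file.path(out_dir, "metrics_example.csv"))
  }
  if ("stats" %in% stages) {
    run_stage("stats", function() {
      if (is.null(study)) study <- simulate_study(cfg$sim)
      bt <- run_stats_battery(study)
      readr::write_csv(bt$anova, file.path(out_dir, "anova.csv"))
      readr::write_csv(bt$posthoc, file.path(out_dir, "posthoc.csv"))
      readr::write_csv(bt$correlations,
                       file.path(out_dir, "correlations.csv"))
      bt
    })
    outputs <- c(outputs, file.path(out_dir, c(
      "anova.csv", "posthoc.csv", "correlations.csv")))
  }
  if ("classify" %in% stages) {
    run_stage("classify", function() {
      if (is.null(study)) study <- simulate_study(cfg$sim)
      w <- window_dataset(study$series, T = cfg$hp$window_length)
      res <- run_loso(w, model = classify_model, hp = cfg$hp)
      readr::write_csv(res$summary, file.path(out_dir, "summary.csv"))
      readr::write_csv(res$per_subject,
                       file.path(out_dir, "per_subject_accuracy.csv"))
      readr::write_csv(res$classwise, file.path(out_dir, "classwise.csv"))
      res
    })
    outputs <- c(outputs, file.path(out_dir, c(
      "summary.csv", "per_subject_accuracy.csv", "classwise.csv")))
  }
  manifest <- list(
    seed = cfg$seed,
    stages = stages,
    config = list(thresholds = unclass(cfg$thresholds),
                  sim = unclass(cfg$sim), hp = unclass(cfg$hp)),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs[file.exists(outputs)])),
      basename(outputs[file.exists(outputs)])))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
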