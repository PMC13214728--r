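flatten_windows <- function(x) {
  d <- dim(x)
  matrix(x, d[1], d[2] * d[3])
}

#' Run leave-one-subject-out cross-validation
#'
#' For each participant: hold out their windows, standardize with
#' train-only statistics, fit the requested model on the remaining
#' participants and evaluate on the held-out windows. The tree-ensemble
#' baselines consume the exact same folds and flattened T x F window
#' vectors.
#'
#' @param windows List with `x`, `y`, `pid` from [window_dataset()].
#' @param model `"lstm"`, `"rf"` (random forest) or `"gbt"`
#'   (gradient-boosted trees).
#' @param hp A [hyperparams()] (used by the LSTM; its `seed` also seeds
#'   the baselines).
#' @param verbose Print per-fold progress.
#' @return List with `reports` (per-fold), `folds`, and the
#'   [summarize_runs()] tables under `summary`, `per_subject`,
#'   `classwise`.
#' @export
run_loso <- function(windows, model = c("lstm", "rf", "gbt"),
                     hp = hyperparams(), verbose = FALSE) {
  model <- match.arg(model)
  folds <- loso_folds(windows$pid)
  reports <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    std <- standardize(windows$x[fold$train_idx, , , drop = FALSE],
                       windows$x[fold$test_idx, , , drop = FALSE])
    ytr <- windows$y[fold$train_idx]
    yte <- windows$y[fold$test_idx]
    prob <- switch(
      model,
      lstm = {
        fit <- train_lstm(std$train, ytr, pid = windows$pid[fold$train_idx],
                          hp = hp)
        predict_lstm(fit, std$test)
      },
      rf = {
        set.seed(hp$seed)
        fit <- randomForest::randomForest(
          x = flatten_windows(std$train), y = factor(ytr, 0:2),
          ntree = 200)
        stats::predict(fit, flatten_windows(std$test), type = "prob")
      },
      gbt = {
        set.seed(hp$seed)
        dtr <- xgboost::xgb.DMatrix(flatten_windows(std$train),
                                    label = ytr)
        fit <- xgboost::xgb.train(
          params = list(objective = "multi:softprob", num_class = 3,
                        max_depth = 4, eta = 0.2, nthread = 1,
                        seed = hp$seed),
          data = dtr, nrounds = 60, verbose = 0)
        pr <- stats::predict(
          fit, xgboost::xgb.DMatrix(flatten_windows(std$test)))
        # xgboost >= 3 returns an n x k matrix; older versions a vector
        if (is.matrix(pr)) pr else matrix(pr, ncol = 3, byrow = TRUE)
      }
    )
    reports[[k]] <- evaluate_predictions(as.matrix(prob), yte,
                                         fold$participant_id)
    if (verbose) {
      message(sprintf("fold %2d (%s): accuracy %.1f%%", k,
                      fold$participant_id, reports[[k]]$accuracy))
    }
  }
  c(list(reports = reports, folds = folds, model = model),
    summarize_runs(reports))
}

#' Compare the LSTM against tree-ensemble baselines
#'
#' Runs random forest and gradient-boosted trees under the identical
#' LOSO folds and reports mean accuracy per model.
#'
#' @param windows List with `x`, `y`, `pid`.
#' @param hp A [hyperparams()].
#' @param models Which models to run.
#' @return Tibble `model, mean_accuracy, sd_accuracy`.
#' @export
run_baselines <- function(windows, hp = hyperparams(),
                          models = c("rf", "gbt")) {
  rows <- lapply(models, function(m) {
    res <- run_loso(windows, model = m, hp = hp)
    acc <- res$summary$mean[res$summary$metric == "accuracy"]
    sdv <- res$summary$sd[res$summary$metric == "accuracy"]
    tibble::tibble(model = m, mean_accuracy = acc, sd_accuracy = sdv)
  })
  dplyr::bind_rows(rows)
}
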