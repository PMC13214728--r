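#' Linearly align metric series to a common length
#'
#' Each session's feature series is linearly resampled onto the index
#' grid of the longest series in the set; endpoints are preserved.
#'
#' @param series_list List of numeric matrices (time steps x channels),
#'   each with >= 2 rows.
#' @return List of matrices, all with `max(nrow)` rows.
#' @export
interpolate_align <- function(series_list) {
  lens <- vapply(series_list, nrow, 1L)
  if (any(lens < 2)) stop("cannot align a single-point series")
  L <- max(lens)
  lapply(series_list, function(m) {
    if (nrow(m) == L) return(m)
    grid <- seq(1, nrow(m), length.out = L)
    apply(m, 2, function(col) stats::approx(seq_len(nrow(m)), col,
                                            xout = grid)$y)
  })
}

#' Build sliding windows from one session
#'
#' Stride-1 windows of `T` consecutive time steps; the label of each
#' window is the session's state label (the label at the final step).
#' Windows never cross session boundaries, so they never mix
#' participants or states.
#'
#' @param features Numeric matrix, time steps x channels.
#' @param label Integer state label (0, 1, 2).
#' @param participant_id Participant the session belongs to.
#' @param T Window length.
#' @return List with `x` (array n x T x F), `y` (labels), `pid`
#'   (participant per window); `NULL` (with a warning) when the session
#'   is shorter than `T`.
#' @export
build_windows <- function(features, label, participant_id, T = 10) {
  L <- nrow(features)
  if (L < T) {
    warning("session of length ", L, " shorter than window ", T,
            "; skipped")
    return(NULL)
  }
  n <- L - T + 1
  x <- array(NA_real_, c(n, T, ncol(features)))
  for (i in seq_len(n)) x[i, , ] <- features[i:(i + T - 1), ]
  list(x = x, y = rep(as.integer(label), n),
       pid = rep(participant_id, n))
}

#' Window an entire simulated study
#'
#' @param series Long series tibble from [simulate_metric_dataset()].
#' @param T Window length.
#' @param channels Feature channels; the default is the four cumulative
#'   eye-tracking metrics. Add `"t"` for the optional timestamp channel.
#' @return List with `x` (n x T x F array), `y`, `pid`.
#' @export
window_dataset <- function(series, T = 10,
                           channels = c("fixation_duration",
                                        "fixation_count",
                                        "saccade_duration",
                                        "saccade_count")) {
  key <- paste(series$participant_id, series$state_label)
  parts <- split(seq_len(nrow(series)), key)
  ws <- lapply(parts, function(idx) {
    s <- series[idx, ]
    s <- s[order(s$step), ]
    build_windows(as.matrix(s[, channels]), s$state_label[1],
                  s$participant_id[1], T)
  })
  ws <- ws[!vapply(ws, is.null, TRUE)]
  x <- do.call(abind1, lapply(ws, `[[`, "x"))
  list(x = x, y = unlist(lapply(ws, `[[`, "y"), use.names = FALSE),
       pid = unlist(lapply(ws, `[[`, "pid"), use.names = FALSE))
}

# bind 3D arrays along the first dimension
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(NA_real_, c(n, d[2], d[3]))
  at <- 1L
  for (a in arrs) {
    k <- dim(a)[1]
    out[at:(at + k - 1), , ] <- a
    at <- at + k
  }
  out
}

#' Train-only channel standardization
#'
#' Per-channel z-scoring with mean and SD computed on the training
#' windows only, then applied to both sets. Channels with zero variance
#' are centered and left at unit divisor (flagged in the result).
#'
#' @param train,test Arrays n x T x F.
#' @return List with standardized `train`, `test`, the `center`/`scale`
#'   used, and `flagged_channels`.
#' @export
standardize <- function(train, test = NULL) {
  F_ <- dim(train)[3]
  center <- numeric(F_); scale <- numeric(F_)
  for (f in seq_len(F_)) {
    v <- train[, , f]
    center[f] <- mean(v)
    scale[f] <- stats::sd(v)
  }
  flagged <- which(scale == 0 | !is.finite(scale))
  scale[flagged] <- 1
  apply_scale <- function(a) {
    if (is.null(a)) return(NULL)
    for (f in seq_len(F_)) a[, , f] <- (a[, , f] - center[f]) / scale[f]
    a
  }
  list(train = apply_scale(train), test = apply_scale(test),
       center = center, scale = scale, flagged_channels = flagged)
}

#' Leave-one-subject-out folds
#'
#' One fold per participant: the held-out participant's windows form
#' the test set, all other participants' windows the training set. The
#' test sets partition the dataset.
#'
#' @param pid Participant id per window.
#' @return List of folds, each with `participant_id`, `train_idx`,
#'   `test_idx`.
#' @export
loso_folds <- function(pid) {
  ids <- sort(unique(pid))
  if (length(ids) < 2) stop("LOSO needs >= 2 participants")
  lapply(ids, function(id) {
    list(participant_id = id,
         train_idx = which(pid != id),
         test_idx = which(pid == id))
  })
}

# rank-statistic (Mann-Whitney) AUC for one score column vs binary truth
binary_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate class predictions on a test set
#'
#' Computes accuracy, macro precision/recall/F1, one-vs-rest macro-AUC
#' from the class probability scores, mean cross-entropy loss, the 3x3
#' confusion matrix and per-class precision/recall/F1. All rates are
#' reported as percentages. When a class is absent from the test set
#' its AUC is skipped and the report is flagged.
#'
#' @param prob n x 3 matrix of class probabilities (columns = labels
#'   0, 1, 2).
#' @param y True integer labels (0, 1, 2).
#' @param participant_id Held-out participant (carried into the report).
#' @return List of class `"fold_report"`.
#' @export
evaluate_predictions <- function(prob, y, participant_id = NA_character_) {
  stopifnot(nrow(prob) == length(y), ncol(prob) == 3)
  classes <- 0:2
  pred <- classes[max.col(prob, ties.method = "first")]
  cm <- table(factor(y, classes), factor(pred, classes))
  acc <- sum(diag(cm)) / sum(cm)
  per_class <- lapply(seq_along(classes), function(k) {
    tp <- cm[k, k]; fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  })
  pc <- do.call(rbind, per_class) * 100
  rownames(pc) <- c("overload", "immersion", "distraction")
  present <- classes %in% y
  aucs <- vapply(seq_along(classes), function(k) {
    binary_auc(prob[, k], y == classes[k])
  }, 0)
  p_true <- prob[cbind(seq_along(y), y + 1L)]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  structure(list(
    participant_id = participant_id,
    accuracy = acc * 100,
    precision_macro = mean(pc[, "precision"][present]),
    recall_macro = mean(pc[, "recall"][present]),
    f1_macro = mean(pc[, "f1"][present]),
    auc_macro = mean(aucs[present], na.rm = TRUE) * 100,
    loss = loss,
    per_class = pc,
    confusion = unclass(cm),
    all_classes_present = all(present)
  ), class = "fold_report")
}

#' Summarize fold reports
#'
#' Mean and sample SD (n - 1) of each metric across folds, a
#' per-participant accuracy listing, and class-wise mean
#' precision/recall/F1 (macro averaging over folds).
#'
#' @param reports List of fold reports from [evaluate_predictions()].
#' @return List with `summary` (tibble metric/mean/sd), `per_subject`
#'   (tibble), `classwise` (tibble).
#' @export
summarize_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  grab <- function(field) vapply(reports, `[[`, 0, field)
  metrics <- c("accuracy", "f1_macro", "recall_macro", "precision_macro",
               "auc_macro", "loss")
  summ <- tibble::tibble(
    metric = metrics,
    mean = unname(vapply(metrics, function(m) mean(grab(m)), 0)),
    sd = unname(vapply(metrics, function(m) {
      if (length(reports) == 1) 0 else stats::sd(grab(m))
    }, 0))
  )
  per_subject <- tibble::tibble(
    participant_id = vapply(reports, `[[`, "", "participant_id"),
    accuracy = grab("accuracy")
  )
  pcs <- lapply(reports, `[[`, "per_class")
  classwise <- tibble::tibble(
    label = rownames(pcs[[1]]),
    precision = rowMeans(vapply(pcs, function(m) m[, "precision"],
                                numeric(3))),
    recall = rowMeans(vapply(pcs, function(m) m[, "recall"], numeric(3))),
    f1 = rowMeans(vapply(pcs, function(m) m[, "f1"], numeric(3)))
  )
  list(summary = summ, per_subject = per_subject, classwise = classwise)
}
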