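test_that("interpolation alignment stretches series onto the longest grid", {
  short <- matrix(c(0, 10), 2, 1)
  long <- matrix(stats::rnorm(3), 3, 1)
  out <- interpolate_align(list(short, long))
  expect_equal(out[[1]][, 1], c(0, 5, 10))  # closed-form linear stretch
  expect_equal(out[[2]], long)              # longest is untouched
  const <- matrix(4, 5, 1)
  out2 <- interpolate_align(list(const, matrix(0, 9, 1)))
  expect_true(all(out2[[1]] == 4))
  expect_error(interpolate_align(list(matrix(1, 1, 1), long)),
               "single-point")
})

test_that("sliding windows follow L - T + 1 with session-pure labels", {
  f <- matrix(stats::rnorm(100 * 4), 100, 4)
  w <- build_windows(f, label = 2, participant_id = "P01", T = 10)
  expect_equal(dim(w$x), c(91, 10, 4))
  expect_equal(unique(w$y), 2L)
  w1 <- build_windows(f[1:10, ], 0, "P01", T = 10)
  expect_equal(dim(w1$x)[1], 1)
  expect_warning(build_windows(f[1:5, ], 0, "P01", T = 10), "skipped")
  st <- tiny_study()
  wd <- window_dataset(st$series, T = 10)
  L <- max(st$series$step)
  n_sessions <- nrow(unique(st$series[, c("participant_id", "state_label")]))
  expect_equal(dim(wd$x)[1], n_sessions * (L - 10 + 1))
  # windows never mix participants: every window has exactly one pid
  expect_equal(length(wd$pid), dim(wd$x)[1])
})

test_that("standardization uses train statistics only", {
  set.seed(9)
  train <- array(stats::rnorm(50 * 10 * 4, mean = 3, sd = 2), c(50, 10, 4))
  test <- array(stats::rnorm(20 * 10 * 4), c(20, 10, 4))
  std <- standardize(train, test)
  for (f in 1:4) {
    expect_equal(mean(std$train[, , f]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(std$train[, , f]), 1, tolerance = 1e-9)
  }
  # shifting test data by c moves standardized values by c / sd_train
  test2 <- test + 5
  std2 <- standardize(train, test2)
  for (f in 1:4) {
    expect_equal(std2$test[, , f] - std$test[, , f],
                 array(5 / std$scale[f], dim(test)[c(1, 2)]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # zero-variance channel is centered, flagged, and left at unit divisor
  train[, , 2] <- 7
  stdz <- standardize(train, test)
  expect_equal(stdz$flagged_channels, 2L)
  expect_true(all(stdz$train[, , 2] == 0))
})

test_that("LOSO folds partition the windows with no participant overlap", {
  pid <- rep(sprintf("P%02d", 1:8), each = 13)
  folds <- loso_folds(pid)
  expect_equal(length(folds), 8)
  all_test <- sort(unlist(lapply(folds, `[[`, "test_idx")))
  expect_equal(all_test, seq_along(pid))
  for (f in folds) {
    expect_length(intersect(f$train_idx, f$test_idx), 0)
    expect_false(f$participant_id %in% pid[f$train_idx])
    expect_true(all(pid[f$test_idx] == f$participant_id))
  }
  expect_error(loso_folds(rep("P1", 5)), ">= 2")
})

test_that("evaluation metrics match hand-computed confusion arithmetic", {
  # perfect predictions
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  prob <- diag(3)[y + 1, ]
  r <- evaluate_predictions(prob, y)
  expect_equal(r$accuracy, 100)
  expect_equal(r$f1_macro, 100)
  expect_equal(r$auc_macro, 100)
  # hand-built confusion: rows true, cols predicted
  #   true 0: 3 correct, 1 -> class 1 ; true 1: 2 correct ; true 2: 1 correct, 1 -> 0
  y2 <- c(0, 0, 0, 0, 1, 1, 2, 2)
  pred2 <- c(0, 0, 0, 1, 1, 1, 0, 2)
  prob2 <- diag(3)[pred2 + 1, ] * 0.8 + 0.1 / 3
  r2 <- evaluate_predictions(prob2, as.integer(y2))
  expect_equal(r2$accuracy, 100 * 6 / 8)
  expect_equal(unname(r2$per_class["overload", "precision"]),
               100 * 3 / 4)   # 3 of 4 predicted-0 correct
  expect_equal(unname(r2$per_class["overload", "recall"]), 100 * 3 / 4)
  expect_equal(unname(r2$per_class["immersion", "precision"]),
               100 * 2 / 3)
  expect_equal(unname(r2$per_class["distraction", "recall"]), 100 * 1 / 2)
  # accuracy recomputed from the confusion matrix equals the reported one
  expect_equal(sum(diag(r2$confusion)) / sum(r2$confusion) * 100,
               r2$accuracy, tolerance = 1e-10)
})

test_that("uniform random scores give chance-level macro-AUC", {
  set.seed(77)
  n <- 3000
  y <- rep(0:2, each = n / 3)
  prob <- matrix(stats::runif(n * 3), n)
  prob <- prob / rowSums(prob)
  r <- evaluate_predictions(prob, y)
  expect_equal(r$auc_macro, 50, tolerance = 3)
})

test_that("rank-based AUC agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rep(0:2, each = 30)
  prob <- matrix(stats::runif(270), 90)
  prob[, 1] <- prob[, 1] + 0.5 * (y == 0)
  prob <- prob / rowSums(prob)
  r <- evaluate_predictions(prob, y)
  aucs <- vapply(0:2, function(k) {
    as.numeric(pROC::auc(pROC::roc(y == k, prob[, k + 1], quiet = TRUE,
                                   direction = "<")))
  }, 0)
  expect_equal(r$auc_macro, mean(aucs) * 100, tolerance = 1e-9)
})

test_that("fold summaries report sample-SD means and per-subject listings", {
  mk <- function(acc, pid) {
    structure(list(participant_id = pid, accuracy = acc,
                   precision_macro = acc, recall_macro = acc,
                   f1_macro = acc, auc_macro = acc, loss = 1,
                   per_class = matrix(acc, 3, 3,
                                      dimnames = list(
                                        c("overload", "immersion",
                                          "distraction"),
                                        c("precision", "recall", "f1"))),
                   confusion = diag(3),
                   all_classes_present = TRUE), class = "fold_report")
  }
  s <- summarize_runs(list(mk(40, "A"), mk(60, "B")))
  expect_equal(s$summary$mean[s$summary$metric == "accuracy"], 50)
  expect_equal(s$summary$sd[s$summary$metric == "accuracy"],
               stats::sd(c(40, 60)))  # sample SD, 14.14
  expect_equal(s$per_subject$accuracy, c(40, 60))
  s1 <- summarize_runs(list(mk(70, "A")))
  expect_true(all(s1$summary$sd == 0))
})
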