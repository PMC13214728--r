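long_from_matrix <- function(Y) {
  states <- colnames(Y)
  if (is.null(states)) states <- c("overload", "immersion", "distraction")
  tibble::tibble(
    participant_id = rep(sprintf("P%02d", seq_len(nrow(Y))), ncol(Y)),
    state = rep(states[seq_len(ncol(Y))], each = nrow(Y)),
    measure = "m", value = c(Y)
  )
}

test_that("rm_anova matches the aov within-subject oracle on random tables", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(c(8, 12, 26), 1)
    Y <- matrix(stats::rnorm(3 * n, mean = rep(c(0, 0.5, 1), each = n)), n)
    res <- rm_anova_matrix(Y)
    df <- data.frame(p = factor(rep(seq_len(n), 3)),
                     s = factor(rep(1:3, each = n)), v = c(Y))
    a <- summary(stats::aov(v ~ s + Error(p / s), df))
    tab <- a[["Error: p:s"]][[1]]
    expect_equal(res$F, tab["s", "F value"], tolerance = 1e-8)
    expect_equal(res$p_uncorrected, tab["s", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(res$eta_p2,
                 tab["s", "Sum Sq"] / (tab["s", "Sum Sq"] +
                                         tab["Residuals", "Sum Sq"]),
                 tolerance = 1e-10)
    expect_equal(res$df1, 2)
    expect_equal(res$df2, 2 * (n - 1))
    expect_gte(res$eps_gg, 0.5)
    expect_lte(res$eps_gg, 1)
    expect_equal(res$df1_gg, res$eps_gg * 2)
  }
})

test_that("rm_anova degenerates gracefully and enforces the design", {
  Y <- matrix(rep(stats::rnorm(8), 3), 8)  # identical condition columns
  res <- rm_anova_matrix(Y)
  expect_equal(res$F, 0)
  expect_equal(res$eta_p2, 0)
  tbl <- long_from_matrix(matrix(stats::rnorm(78), 26))
  expect_equal(rm_anova(tbl, "m")$df2, 50)
  expect_error(rm_anova(tbl[-1, ], "m"), "incomplete")
})

test_that("GG epsilon is 1 under compound symmetry and bounded below", {
  S <- 0.3 + diag(0.7, 3)  # compound symmetric
  expect_equal(gg_epsilon(S), 1)
  set.seed(2)
  for (i in 1:20) {
    A <- matrix(stats::rnorm(9), 3)
    eps <- gg_epsilon(crossprod(A) + diag(1e-6, 3))
    expect_gte(eps, 0.5)
    expect_lte(eps, 1)
  }
  expect_error(gg_epsilon(matrix(0, 3, 3)), "degenerate")
})

test_that("GG-corrected and uncorrected p agree when sphericity holds", {
  set.seed(30)
  b <- stats::rnorm(40, sd = 2)
  Y <- b + matrix(stats::rnorm(120, mean = rep(c(0, 0.3, 0.6), each = 40)),
                  40)
  res <- rm_anova_matrix(Y)
  expect_gt(res$eps_gg, 0.85)
  expect_equal(res$p_gg, res$p_uncorrected,
               tolerance = 10 * abs(res$p_uncorrected) + 0.02)
})

test_that("Mauchly's W matches the stats::mauchly.test oracle", {
  set.seed(7)
  Y <- matrix(stats::rnorm(78), 26, 3) %*%
    matrix(c(1, .3, .1, .3, 1, .5, .1, .5, 1), 3)
  got <- mauchly_sphericity(Y)
  want <- stats::mauchly.test(stats::lm(Y ~ 1), X = ~1)
  expect_equal(got$W, unname(want$statistic), tolerance = 1e-10)
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
})

test_that("paired post hocs match the difference-score t oracle", {
  set.seed(5)
  Y <- matrix(stats::rnorm(30, mean = rep(c(0, 1, 2), each = 10)), 10)
  colnames(Y) <- c("distraction", "immersion", "overload")
  ph <- posthoc_bonferroni(long_from_matrix(Y))
  d12 <- Y[, 1] - Y[, 2]
  oracle <- mean(d12) / (stats::sd(d12) / sqrt(10))
  expect_equal(ph$t[1], oracle, tolerance = 1e-10)
  expect_equal(ph$p_bonf,
               pmin(1, 3 * ph$p_paired), tolerance = 1e-12)
  expect_equal(ph$pair, c("distraction vs immersion",
                          "distraction vs overload",
                          "immersion vs overload"))
  # swapping two conditions flips t's sign, leaves p and d unchanged
  Y2 <- Y[, c(2, 1, 3)]
  colnames(Y2) <- colnames(Y)
  ph2 <- posthoc_bonferroni(long_from_matrix(Y2))
  expect_equal(ph2$t[1], -ph$t[1], tolerance = 1e-10)
  expect_equal(ph2$p_paired[1], ph$p_paired[1], tolerance = 1e-12)
  expect_equal(ph2$d[1], ph$d[1], tolerance = 1e-12)
  # identical conditions -> degenerate flag, p_bonf = 1
  Y3 <- matrix(rep(stats::rnorm(6), 3), 6)
  colnames(Y3) <- colnames(Y)
  ph3 <- posthoc_bonferroni(long_from_matrix(Y3))
  expect_true(all(ph3$p_bonf == 1))
  expect_true(all(ph3$degenerate))
})

test_that("Cohen's d uses the RMS-of-SDs convention", {
  expect_equal(cohens_d(5.256, 2.29, 8.974, 5.393), 0.897,
               tolerance = 0.001)
  expect_equal(cohens_d(5.45, 1.16, 2.25, 0.93), 3.04, tolerance = 0.005)
  expect_equal(cohens_d(3, 1, 3, 2), 0)
  expect_error(cohens_d(1, 0, 2, 1), "positive")
})

test_that("Pearson correlation matches the direct covariance formula", {
  x <- 1:10
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  set.seed(44)
  a <- stats::rnorm(78); b <- 0.4 * a + stats::rnorm(78)
  got <- pearson_with_p(a, b)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, oracle, tolerance = 1e-12)
  expect_equal(got$n, 78)
  expect_error(pearson_with_p(rep(1, 5), stats::rnorm(5)), "zero variance")
})

test_that("the full battery yields positive IL-metric correlations", {
  st <- simulate_study(simulation_spec(seed = 2))
  bt <- run_stats_battery(st)
  il <- bt$correlations[bt$correlations$scale == "il", ]
  expect_equal(nrow(il), 4)
  expect_true(all(il$r > 0))
  expect_true(all(bt$anova$df1 == 2 & bt$anova$df2 == 50))
  expect_true(all(bt$anova$eta_p2 >= 0 & bt$anova$eta_p2 <= 1))
})
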