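#' Reshape a long session table to a participant-by-condition matrix
#'
#' @param table Long tibble with columns `participant_id`, `state` (or
#'   `state_label`) and `value` (optionally filtered by `measure`).
#' @param measure Optional measure name to filter on.
#' @return Numeric matrix, rows = participants, columns = conditions.
#' @keywords internal
condition_matrix <- function(table, measure = NULL) {
  if (!is.null(measure)) table <- table[table$measure == measure, ]
  state <- if ("state" %in% names(table)) table$state else table$state_label
  wide <- tapply(table$value, list(table$participant_id, state), identity)
  if (anyNA(wide)) stop("incomplete within-subject design: missing cells")
  m <- matrix(unlist(wide), nrow(wide), ncol(wide),
              dimnames = dimnames(wide))
  if (nrow(m) < 2 || ncol(m) != 3) {
    stop("need >= 2 participants and exactly 3 states")
  }
  m
}

#' Greenhouse-Geisser epsilon
#'
#' Epsilon-hat from the sample covariance matrix of the condition
#' scores: with `S` double-centered, `eps = (sum diag S)^2 /
#' ((k - 1) * sum(S^2))`. Bounded in `[1/(k-1), 1]`.
#'
#' @param S k-by-k covariance matrix of the condition scores.
#' @return Greenhouse-Geisser epsilon.
#' @export
gg_epsilon <- function(S) {
  k <- ncol(S)
  stopifnot(k >= 2, nrow(S) == k)
  if (any(!is.finite(S)) || all(abs(S) < 1e-300)) {
    stop("degenerate condition covariance")
  }
  C <- diag(k) - 1 / k
  D <- C %*% S %*% C
  eps <- sum(diag(D))^2 / ((k - 1) * sum(D^2))
  min(1, max(1 / (k - 1), eps))
}

#' Mauchly's test of sphericity
#'
#' W statistic on the orthonormal-contrast covariance with the standard
#' chi-square approximation on k(k-1)/2 - 1 degrees of freedom.
#'
#' @param Y n-by-k condition-score matrix.
#' @return List with `W`, `chisq`, `df`, `p`.
#' @export
mauchly_sphericity <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  C <- contrast_basis(k)
  S <- stats::cov(Y)
  T0 <- C %*% S %*% t(C)
  W <- det(T0) / (sum(diag(T0)) / (k - 1))^(k - 1)
  df <- k * (k - 1) / 2 - 1
  rho <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
  chisq <- -(n - 1) * rho * log(W)
  list(W = W, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

# orthonormal basis of contrasts (k-1 x k), rows orthonormal, each
# orthogonal to the unit vector
contrast_basis <- function(k) {
  H <- stats::contr.helmert(k)
  t(apply(t(H), 1, function(r) r / sqrt(sum(r^2))))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test for a complete participant x condition design,
#' with Mauchly's sphericity test, the Greenhouse-Geisser correction
#' (always reported alongside the uncorrected p) and partial eta
#' squared `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table Long tibble (`participant_id`, `state`/`state_label`,
#'   `measure`, `value`).
#' @param measure Measure to analyse.
#' @return List of class `"rm_anova"` with `F`, `df1`, `df2`,
#'   `eps_gg`, `df1_gg`, `df2_gg`, `p_uncorrected`, `p_gg`, `eta_p2`,
#'   `sphericity_W`, `sphericity_p`, `n`, `k`.
#' @export
rm_anova <- function(table, measure = NULL) {
  Y <- condition_matrix(table, measure)
  res <- rm_anova_matrix(Y)
  res$measure <- measure
  res
}

#' @rdname rm_anova
#' @param Y n-by-k condition-score matrix (participants in rows).
#' @export
rm_anova_matrix <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  cond_means <- colMeans(Y)
  subj_means <- rowMeans(Y)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  F <- if (ms_err == 0) 0 else ms_cond / ms_err
  eps <- gg_epsilon(stats::cov(Y))
  sph <- mauchly_sphericity(Y)
  structure(list(
    F = F, df1 = df1, df2 = df2,
    eps_gg = eps, df1_gg = eps * df1, df2_gg = eps * df2,
    p_uncorrected = stats::pf(F, df1, df2, lower.tail = FALSE),
    p_gg = stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE),
    eta_p2 = if (ss_cond + ss_err == 0) 0 else ss_cond / (ss_cond + ss_err),
    ss_effect = ss_cond, ss_error = ss_err,
    sphericity_W = sph$W, sphericity_p = sph$p,
    n = n, k = k
  ), class = "rm_anova")
}

#' Cohen's d from summary statistics
#'
#' Pooled-SD convention: `d = |m1 - m2| / sqrt((s1^2 + s2^2) / 2)`,
#' the root-mean-square of the two condition SDs in the denominator.
#'
#' @param m1,s1 Mean and SD of condition 1.
#' @param m2,s2 Mean and SD of condition 2.
#' @return Nonnegative effect size d.
#' @export
cohens_d <- function(m1, s1, m2, s2) {
  if (any(c(s1, s2) <= 0)) stop("standard deviations must be positive")
  abs(m1 - m2) / sqrt((s1^2 + s2^2) / 2)
}

#' Bonferroni-corrected paired post hoc comparisons
#'
#' Paired t-tests for the three state pairs (distraction vs immersion,
#' distraction vs overload, immersion vs overload), p-values multiplied
#' by 3 and capped at 1, with the pooled-SD Cohen's d and a normal-
#' approximation 95% CI on the signed standardized difference
#' (`d_signed +/- 1.96 * se`, `se^2 = 2(1 - r)/n + d^2 / (2(n - 1))`
#' where `r` is the condition-pair correlation).
#'
#' @param table Long tibble (see [rm_anova()]).
#' @param measure Measure to analyse.
#' @return Tibble: `measure, pair, t, df, p_paired, p_bonf, d,
#'   ci_lower, ci_upper, degenerate`.
#' @export
posthoc_bonferroni <- function(table, measure = NULL) {
  Y <- condition_matrix(table, measure)
  cols <- colnames(Y)
  ord <- c("distraction", "immersion", "overload")
  if (all(ord %in% cols)) Y <- Y[, ord]
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  n <- nrow(Y)
  rows <- lapply(pairs, function(pr) {
    a <- Y[, pr[1]]; b <- Y[, pr[2]]
    diffs <- a - b
    degenerate <- stats::sd(diffs) == 0
    if (degenerate) {
      tt <- list(statistic = c(t = 0), parameter = c(df = n - 1),
                 p.value = 1)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
    }
    d <- cohens_d(mean(a), stats::sd(a), mean(b), stats::sd(b))
    d_signed <- (mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
    r <- suppressWarnings(stats::cor(a, b))
    if (!is.finite(r)) r <- 0
    se <- sqrt(2 * (1 - r) / n + d_signed^2 / (2 * (n - 1)))
    tibble::tibble(
      measure = measure %||% NA_character_,
      pair = paste(colnames(Y)[pr[1]], "vs", colnames(Y)[pr[2]]),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_paired = tt$p.value, p_bonf = min(1, 3 * tt$p.value),
      d = d,
      ci_lower = d_signed - 1.96 * se, ci_upper = d_signed + 1.96 * se,
      degenerate = degenerate
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation with two-tailed p
#'
#' Product-moment correlation with the t-transform p-value on n - 2
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}

#' Run the full statistical battery on a simulated study
#'
#' Descriptives, RM-ANOVA (with GG correction), Bonferroni post hocs
#' and pooled metric-scale Pearson correlations, mirroring the standard
#' reporting for a three-state within-subject design.
#'
#' @param study Output of [simulate_study()], or a list with
#'   `aggregates` and `questionnaires` long tibbles.
#' @return List of tibbles: `descriptives`, `anova`, `posthoc`,
#'   `correlations`.
#' @export
run_stats_battery <- function(study) {
  long <- dplyr::bind_rows(study$aggregates, study$questionnaires)
  measures <- unique(long$measure)
  desc <- long |>
    dplyr::group_by(.data$measure, .data$state) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  anova <- dplyr::bind_rows(lapply(measures, function(m) {
    a <- rm_anova(long, m)
    tibble::tibble(measure = m, F = a$F, df1 = a$df1, df2 = a$df2,
                   df1_gg = a$df1_gg, df2_gg = a$df2_gg,
                   eps_gg = a$eps_gg, p_uncorrected = a$p_uncorrected,
                   p_gg = a$p_gg, stars = significance_stars(a$p_gg),
                   eta_p2 = a$eta_p2, sphericity_W = a$sphericity_W,
                   sphericity_p = a$sphericity_p)
  }))
  posthoc <- dplyr::bind_rows(lapply(measures, function(m) {
    ph <- posthoc_bonferroni(long, m)
    ph$stars <- significance_stars(ph$p_bonf)
    ph
  }))
  metric_names <- unique(study$aggregates$measure)
  scale_names <- unique(study$questionnaires$measure)
  wide <- tidyr::pivot_wider(long, id_cols = c("participant_id", "state"),
                             names_from = "measure", values_from = "value")
  correlations <- dplyr::bind_rows(lapply(scale_names, function(sc) {
    dplyr::bind_rows(lapply(metric_names, function(mt) {
      ct <- pearson_with_p(wide[[sc]], wide[[mt]])
      tibble::tibble(scale = sc, metric = mt, r = ct$r, p = ct$p,
                     n = ct$n, stars = significance_stars(ct$p))
    }))
  }))
  list(descriptives = desc, anova = anova, posthoc = posthoc,
       correlations = correlations)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "RM-ANOVA%s: F(%d, %d) = %.2f, p = %.4g; GG eps = %.3f, F(%.2f, %.2f), p_GG = %.4g; eta_p2 = %.3f\n",
    if (is.null(x$measure)) "" else paste0(" [", x$measure, "]"),
    x$df1, x$df2, x$F, x$p_uncorrected, x$eps_gg, x$df1_gg, x$df2_gg,
    x$p_gg, x$eta_p2))
  invisible(x)
}
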