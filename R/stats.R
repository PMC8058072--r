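# Rank-based statistics used throughout the pipeline: Mann-Whitney U,
# ROC/AUC, Youden cutoffs, Spearman correlation, categorical tests.
# These are the evaluation primitives; cohort-level wrappers live in
# screen.R and pipeline.R.

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Computes the Mann-Whitney U statistic for `x` relative to `y` using
#' midranks for ties, with a two-sided p-value. When the pooled sample size
#' is at most `exact_max` the p-value is exact, obtained by enumerating all
#' \eqn{\binom{n_x+n_y}{n_x}} group assignments of the pooled values
#' (midranks make the enumeration valid in the presence of ties) and
#' doubling the smaller tail probability, capped at 1. For larger samples a
#' normal approximation with tie correction and a 0.5 continuity correction
#' is used.
#'
#' @param x,y Numeric vectors of observations for the two groups.
#' @param exact_max Largest pooled sample size for which the exact
#'   enumeration p-value is computed. Default 12.
#' @return A one-row tibble with columns `statistic_name` (`"U"`),
#'   `statistic`, `p_value`, `method`, `n_x`, `n_y`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    abort("`x` and `y` must both be non-empty.")
  }
  if (anyNA(x) || anyNA(y)) abort("`x` and `y` must not contain NA.")
  n1 <- length(x)
  n2 <- length(y)
  nn <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (nn <= exact_max) {
    idx <- combn(nn, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u + 1e-12),
                        mean(u_all >= u - 1e-12)))
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  tibble(
    statistic_name = "U", statistic = u, p_value = p,
    method = method, n_x = n1, n_y = n2
  )
}

# rank-sum AUC: P(case > control) + 0.5 P(case = control)
auc_rank <- function(case_scores, control_scores) {
  n1 <- length(case_scores)
  n2 <- length(control_scores)
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve analysis with AUC and confidence interval
#'
#' The AUC is the probability that a random case scores above a random
#' control, with ties counted one half: equivalently the Mann-Whitney
#' \eqn{U/(n_1 n_2)}. The 95% (or `level`) confidence interval is a
#' group-stratified percentile bootstrap by default; the analytic
#' Hanley-McNeil interval is available for comparison. The Youden-optimal
#' cutoff and its sensitivity/specificity are reported alongside.
#'
#' @param case_scores,control_scores Numeric score vectors; higher scores
#'   are taken to indicate case status.
#' @param ci_method `"bootstrap"` (stratified percentile), `"hanley"`
#'   (Hanley-McNeil normal-theory interval), or `"none"` (skip the CI;
#'   `ci_low`/`ci_high` are `NA`).
#' @param B Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return A one-row tibble of class `roc_result`: `auc`, `ci_low`,
#'   `ci_high`, `ci_method`, `cutoff`, `sensitivity`, `specificity`,
#'   `n_case`, `n_control`. The full ROC coordinates are attached as
#'   attribute `"curve"` (see [roc_curve_points()]).
#' @seealso [optimal_cutoff()], [autoplot.roc_result()]
#' @export
roc_auc <- function(case_scores, control_scores,
                    ci_method = c("bootstrap", "hanley", "none"),
                    B = 2000L, level = 0.95, seed = 1L) {
  ci_method <- arg_match(ci_method)
  case_scores <- as.numeric(case_scores)
  control_scores <- as.numeric(control_scores)
  if (length(case_scores) == 0L || length(control_scores) == 0L) {
    abort("Both score vectors must be non-empty.")
  }
  n1 <- length(case_scores)
  n2 <- length(control_scores)
  a <- auc_rank(case_scores, control_scores)

  if (ci_method == "bootstrap") {
    boot <- withr::with_seed(seed, {
      vapply(seq_len(B), function(b) {
        auc_rank(
          sample(case_scores, n1, replace = TRUE),
          sample(control_scores, n2, replace = TRUE)
        )
      }, numeric(1))
    })
    qs <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE, type = 7)
    lo <- min(qs[1], a)
    hi <- max(qs[2], a)
  } else if (ci_method == "none") {
    lo <- NA_real_
    hi <- NA_real_
  } else {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                  (n2 - 1) * (q2 - a^2)) / (n1 * n2))
    z <- qnorm(1 - (1 - level) / 2)
    lo <- max(0, a - z * se)
    hi <- min(1, a + z * se)
  }

  cut <- optimal_cutoff(case_scores, control_scores)
  out <- tibble(
    auc = a, ci_low = lo, ci_high = hi, ci_method = ci_method,
    cutoff = cut$cutoff, sensitivity = cut$sensitivity,
    specificity = cut$specificity, n_case = n1, n_control = n2
  )
  attr(out, "curve") <- roc_curve_points(case_scores, control_scores)
  class(out) <- c("roc_result", class(out))
  out
}

#' ROC curve coordinates
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct threshold (classification rule: score >= threshold is called
#'   a case).
#' @export
roc_curve_points <- function(case_scores, control_scores) {
  th <- c(Inf, sort(unique(c(case_scores, control_scores)), decreasing = TRUE))
  tibble(
    threshold = th,
    fpr = vapply(th, function(t) mean(control_scores >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(case_scores >= t), numeric(1))
  )
}

#' Youden-optimal classification cutoff
#'
#' Sweeps all candidate thresholds (the smallest observed score plus every
#' midpoint between adjacent distinct pooled scores) and returns the one
#' maximizing Youden's J = sensitivity + specificity - 1 under the rule
#' score >= cutoff => case. Ties in J are broken toward higher sensitivity,
#' then toward the lower cutoff.
#'
#' @inheritParams roc_auc
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
optimal_cutoff <- function(case_scores, control_scores) {
  case_scores <- as.numeric(case_scores)
  control_scores <- as.numeric(control_scores)
  if (length(case_scores) == 0L || length(control_scores) == 0L) {
    abort("Both score vectors must be non-empty.")
  }
  v <- sort(unique(c(case_scores, control_scores)))
  cands <- if (length(v) == 1L) v else c(v[1], (v[-1] + v[-length(v)]) / 2)
  sens <- vapply(cands, function(t) mean(case_scores >= t), numeric(1))
  spec <- vapply(cands, function(t) mean(control_scores < t), numeric(1))
  j <- sens + spec - 1
  # order: max J, then max sensitivity, then min cutoff
  best <- order(-j, -sens, cands)[1]
  tibble(
    cutoff = cands[best], sensitivity = sens[best],
    specificity = spec[best], youden_j = j[best]
  )
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples rows of `data` with replacement `B` times (within strata when
#' `strata` is given), applies `statistic` to each resample, and returns the
#' percentile interval of the resulting distribution. Resamples on which the
#' statistic is undefined (returns `NA`) are redrawn and counted.
#'
#' @param data A vector or data frame of observations.
#' @param statistic A function mapping a resample of `data` to a single
#'   number.
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param strata Optional vector (same length/rows as `data`); resampling is
#'   done independently within each stratum, preserving stratum sizes.
#' @param seed Integer seed.
#' @return A one-row tibble: `lower`, `upper`, `level`, `B`, `n_redrawn`.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000L, level = 0.95,
                         strata = NULL, seed = 1L) {
  if (B < 100L) abort("`B` must be at least 100.")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- function(d, i) if (is.data.frame(d)) d[i, , drop = FALSE] else d[i]
  groups <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
  n_redrawn <- 0L
  stats <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in seq_len(100L)) {
        idx <- unlist(lapply(groups, function(g) {
          sample(g, length(g), replace = TRUE)
        }), use.names = FALSE)
        val <- statistic(take(data, idx))
        if (!is.na(val)) {
          if (try > 1L) n_redrawn <<- n_redrawn + (try - 1L)
          return(as.numeric(val))
        }
      }
      abort("`statistic` was undefined on 100 consecutive resamples.")
    }, numeric(1))
  })
  qs <- quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  tibble(lower = qs[1], upper = qs[2], level = level, B = B,
         n_redrawn = n_redrawn)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the
#' t approximation \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric (or ordered-factor) vectors of equal length >= 3.
#' @return A one-row tibble: `r`, `n`, `p_value`.
#' @export
spearman_cor <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n) {
    abort("`x` and `y` must have equal length >= 3 after removing NAs.")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("Zero rank variance; Spearman correlation undefined.")
    return(tibble(r = NA_real_, n = n, p_value = NA_real_))
  }
  r <- stats::cor(rx, ry)
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  tibble(r = r, n = n, p_value = p)
}

#' Test of association in a 2x2 contingency table
#'
#' Applies the Pearson chi-square test (no continuity correction) when
#' every expected cell count exceeds 5, and Fisher's exact test
#' (two-sided, summing hypergeometric probabilities no larger than that of
#' the observed table) otherwise.
#'
#' @param tab A 2x2 matrix or table of non-negative integer counts.
#' @return A one-row tibble: `method`, `statistic_name`, `statistic`
#'   (chi-square statistic, or the conditional odds-ratio estimate for
#'   Fisher's test), `p_value`.
#' @examples
#' categorical_test(matrix(c(15, 4, 135, 39), nrow = 2))
#' @export
categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) abort("`tab` must be a 2x2 table.")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must contain non-negative integer counts.")
  }
  if (sum(tab) == 0) abort("`tab` must contain at least one observation.")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) {
    ft <- fisher.test(tab)
    tibble(method = "fisher_exact", statistic_name = "odds_ratio",
           statistic = unname(ft$estimate), p_value = ft$p.value)
  } else {
    ct <- chisq.test(tab, correct = FALSE)
    tibble(method = "pearson_chisq", statistic_name = "X_squared",
           statistic = unname(ct$statistic), p_value = ct$p.value)
  }
}
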