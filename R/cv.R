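# k-fold cross-validated ROC evaluation of a single marker score, with
# bootstrap confidence intervals for the mean fold AUCs.

#' Stratified k-fold cross-validated AUC
#'
#' Splits subjects into `k` label-stratified folds (seeded). Within each
#' fold the marker score is evaluated directly by ROC analysis on both the
#' training portion (the other k - 1 folds) and the held-out test portion;
#' no model is fitted, since a single-marker score needs no trained
#' classifier. The reported train and test AUCs are the arithmetic means
#' over folds, with percentile bootstrap confidence intervals obtained by
#' resampling subjects within class and re-running the full k-fold
#' procedure on each resample.
#'
#' @param scores Numeric vector of per-subject marker scores (higher =
#'   more case-like).
#' @param labels Logical vector (or factor/character coercible to it) the
#'   same length as `scores`; `TRUE`/`"case"` marks cases.
#' @param k Number of folds (default 5).
#' @param B Number of bootstrap resamples for the CIs (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed controlling fold assignment and the bootstrap.
#' @return An object of class `cv_result`: a list with `k`,
#'   `fold_train_aucs`, `fold_test_aucs`, `mean_train_auc`,
#'   `mean_test_auc`, `boot_ci_train`, `boot_ci_test` (each `c(lower,
#'   upper)`), `n_boot`, `level`, `n_case`, `n_control`, `seed`. Use
#'   [tidy()] for the per-fold table and [glance()] for the one-row
#'   summary.
#' @export
kfold_cross_validate <- function(scores, labels, k = 5L, B = 1000L,
                                 level = 0.95, seed = 1L) {
  scores <- as.numeric(scores)
  is_case <- as_case_logical(labels)
  if (length(scores) != length(is_case)) {
    abort("`scores` and `labels` must have equal length.")
  }
  keep <- !is.na(scores) & !is.na(is_case)
  scores <- scores[keep]
  is_case <- is_case[keep]
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (min(n1, n2) < k) {
    abort(sprintf(
      "Each class must have at least k = %d members (got %d cases, %d controls).",
      k, n1, n2
    ))
  }

  run_cv <- function(scores, is_case, fold_seed) {
    folds <- withr::with_seed(fold_seed, stratified_folds(is_case, k))
    tr <- te <- numeric(k)
    for (i in seq_len(k)) {
      test <- folds == i
      tr[i] <- auc_rank(scores[!test & is_case], scores[!test & !is_case])
      te[i] <- auc_rank(scores[test & is_case], scores[test & !is_case])
    }
    list(train = tr, test = te)
  }

  main <- run_cv(scores, is_case, seed)

  idx_case <- which(is_case)
  idx_control <- which(!is_case)
  boot <- withr::with_seed(seed + 1L, {
    t(vapply(seq_len(B), function(b) {
      idx <- c(sample(idx_case, n1, replace = TRUE),
               sample(idx_control, n2, replace = TRUE))
      res <- run_cv(scores[idx], is_case[idx], sample.int(2^30, 1L))
      c(mean(res$train), mean(res$test))
    }, numeric(2)))
  })
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  structure(list(
    k = k,
    fold_train_aucs = main$train,
    fold_test_aucs = main$test,
    mean_train_auc = mean(main$train),
    mean_test_auc = mean(main$test),
    boot_ci_train = unname(quantile(boot[, 1], probs)),
    boot_ci_test = unname(quantile(boot[, 2], probs)),
    n_boot = B,
    level = level,
    n_case = n1,
    n_control = n2,
    seed = seed
  ), class = "cv_result")
}

# fold ids 1..k, stratified by class; caller controls the RNG state
stratified_folds <- function(is_case, k) {
  folds <- integer(length(is_case))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_case == cls)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels == "case")
  if (is.numeric(labels)) return(labels != 0)
  abort("`labels` must be logical, factor, character or numeric.")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold cross-validated AUC (%d cases / %d controls)\n", x$k,
    x$n_case, x$n_control
  ))
  cat(sprintf("  train: mean AUC %.3f [%.3f-%.3f]\n", x$mean_train_auc,
              x$boot_ci_train[1], x$boot_ci_train[2]))
  cat(sprintf("  test:  mean AUC %.3f [%.3f-%.3f]\n", x$mean_test_auc,
              x$boot_ci_test[1], x$boot_ci_test[2]))
  cat(sprintf("  bootstrap: %d resamples, %.0f%% percentile CI\n",
              x$n_boot, 100 * x$level))
  invisible(x)
}

#' @describeIn kfold_cross_validate one row per fold with train/test AUC.
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) {
  tibble(
    fold = seq_len(x$k),
    train_auc = x$fold_train_aucs,
    test_auc = x$fold_test_aucs
  )
}

#' @describeIn kfold_cross_validate one-row summary with mean AUCs and CIs.
#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    k = x$k,
    mean_train_auc = x$mean_train_auc,
    train_ci_low = x$boot_ci_train[1],
    train_ci_high = x$boot_ci_train[2],
    mean_test_auc = x$mean_test_auc,
    test_ci_low = x$boot_ci_test[1],
    test_ci_high = x$boot_ci_test[2],
    n_boot = x$n_boot,
    n_case = x$n_case,
    n_control = x$n_control
  )
}
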