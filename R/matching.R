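# Propensity-score matching on age and sex: logistic propensity model
# (with a Firth bias-reduced fallback under separation), greedy 1:ratio
# nearest-neighbor matching within a caliper on the logit scale, and
# covariate-balance diagnostics via standardized differences.

#' Fit a propensity-score model
#'
#' Maximum-likelihood logistic regression of case status on the given
#' covariates. Constant covariates are dropped with a warning. If the fit
#' shows complete or quasi-complete separation (fitted probabilities
#' numerically 0/1 or non-convergence), the model is refitted by Firth's
#' bias-reduced logistic regression and flagged. The model's C-statistic is
#' the rank-based AUC of the propensity score against group labels.
#'
#' @param subjects A subject tibble with columns `subject_id`, `group`
#'   (factor with levels control/case) and the covariates.
#' @param covariates Character vector of covariate column names
#'   (default `c("age", "sex")`).
#' @return An object of class `ps_model`: list with `scores` (tibble:
#'   `subject_id`, `group`, `ps`, `logit_ps`), `coefficients`,
#'   `c_statistic`, `method` (`"ml"` or `"firth"`), `covariates`, and the
#'   `subjects` used. Supports [tidy()] and [glance()].
#' @export
fit_propensity <- function(subjects, covariates = c("age", "sex")) {
  if (!all(covariates %in% names(subjects))) {
    abort("All `covariates` must be columns of `subjects`.")
  }
  if (any(!stats::complete.cases(subjects[covariates]))) {
    abort("Covariates must be present (non-NA) for all subjects.")
  }
  y <- as_case_logical(subjects$group)
  if (sum(y) < 2L || sum(!y) < 2L) {
    abort("Need at least 2 subjects per group to fit a propensity model.")
  }

  keep <- covariates[vapply(covariates, function(v) {
    length(unique(subjects[[v]])) > 1L
  }, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped)) {
    warn(paste0("Dropping constant covariate(s): ",
                paste(dropped, collapse = ", ")))
  }

  if (length(keep) == 0L) {
    p <- rep(mean(y), length(y))
    coefs <- c("(Intercept)" = qlogis(mean(y)))
    method <- "ml"
  } else {
    mm <- stats::model.matrix(
      stats::reformulate(keep),
      data = as.data.frame(subjects[keep])
    )
    fit <- suppressWarnings(stats::glm.fit(mm, y, family = binomial()))
    p <- fit$fitted.values
    separated <- !fit$converged || any(p > 1 - 1e-8) || any(p < 1e-8) ||
      any(abs(coef(fit)) > 15)
    if (separated) {
      warn("Separation detected; using Firth bias-reduced logistic fit.")
      fr <- firth_logistic(mm, y)
      p <- fr$fitted
      coefs <- fr$coefficients
      method <- "firth"
    } else {
      coefs <- coef(fit)
      method <- "ml"
    }
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  scores <- tibble(
    subject_id = subjects$subject_id,
    group = subjects$group,
    ps = unname(p),
    logit_ps = qlogis(unname(p))
  )
  structure(list(
    scores = scores,
    coefficients = coefs,
    c_statistic = auc_rank(p[y], p[!y]),
    method = method,
    covariates = covariates,
    subjects = subjects
  ), class = "ps_model")
}

# Firth bias-reduced logistic regression by Newton iteration on the
# modified score U* = X'(y - p + h (1/2 - p)), h = hat diagonal.
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    XtW <- t(X * w)
    info <- XtW %*% X
    inv_info <- solve(info + diag(1e-12, ncol(X)))
    h <- rowSums((X %*% inv_info) * X) * w
    score <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- drop(inv_info %*% score)
    # dampen huge steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  p <- plogis(drop(X %*% beta))
  list(coefficients = stats::setNames(beta, colnames(X)), fitted = p)
}

#' @describeIn fit_propensity coefficient table.
#' @param x A `ps_model`.
#' @param ... Unused.
#' @export
tidy.ps_model <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @describeIn fit_propensity one-row model summary.
#' @export
glance.ps_model <- function(x, ...) {
  tibble(
    c_statistic = x$c_statistic,
    n = nrow(x$scores),
    n_case = sum(as_case_logical(x$scores$group)),
    method = x$method
  )
}

#' @export
print.ps_model <- function(x, ...) {
  cat(sprintf("Propensity model (%s) on %s\n", x$method,
              paste(x$covariates, collapse = " + ")))
  cat(sprintf("  C-statistic: %.3f (n = %d)\n", x$c_statistic,
              nrow(x$scores)))
  invisible(x)
}

#' Greedy nearest-neighbor caliper matching on the propensity score
#'
#' Matches each case to up to `ratio` controls by nearest |logit PS|
#' distance, within a caliper of `caliper_multiplier` times the SD of the
#' logit propensity score. Cases are visited in seeded random order; each
#' takes its nearest remaining in-caliper controls (without replacement by
#' default). Distance ties are broken by subject id so matching is fully
#' deterministic given the seed.
#'
#' @param model A [fit_propensity()] result.
#' @param ratio Controls per case (default 4).
#' @param caliper_multiplier Caliper width as a multiple of the logit-PS SD
#'   (default 0.2).
#' @param with_replacement Allow a control to be reused (default `FALSE`).
#' @param sd_scope `"pooled"` (SD of the logit over all subjects, the
#'   default) or `"within"` (square root of the mean of the within-group
#'   variances).
#' @param seed Integer seed for the case processing order.
#' @return An object of class `match_result`: `matched_sets` (tibble:
#'   `case_id`, `control_id`, `rank`, `distance`), `caliper_width`,
#'   `unmatched_cases`, `balance` (a [balance_table()] on the model's
#'   covariates), plus the matching parameters.
#' @export
match_nearest_neighbor <- function(model, ratio = 4L,
                                   caliper_multiplier = 0.2,
                                   with_replacement = FALSE,
                                   sd_scope = c("pooled", "within"),
                                   seed = 1L) {
  if (!inherits(model, "ps_model")) abort("`model` must be a ps_model.")
  if (ratio < 1) abort("`ratio` must be >= 1.")
  if (caliper_multiplier <= 0) abort("`caliper_multiplier` must be > 0.")
  sd_scope <- arg_match(sd_scope)

  sc <- model$scores
  is_case <- as_case_logical(sc$group)
  if (!any(!is_case)) abort("No controls available for matching.",
                            class = "uromir_empty_match_error")
  lp <- sc$logit_ps
  sd_logit <- if (sd_scope == "pooled") {
    sd(lp)
  } else {
    sqrt((var(lp[is_case]) + var(lp[!is_case])) / 2)
  }
  caliper <- caliper_multiplier * sd_logit

  case_ids <- sc$subject_id[is_case]
  case_lp <- lp[is_case]
  ctrl_ids <- sc$subject_id[!is_case]
  ctrl_lp <- lp[!is_case]
  # deterministic tie-break: pre-sort controls by id
  o <- order(ctrl_ids)
  ctrl_ids <- ctrl_ids[o]
  ctrl_lp <- ctrl_lp[o]

  order_cases <- withr::with_seed(seed, sample(seq_along(case_ids)))
  available <- rep(TRUE, length(ctrl_ids))
  sets <- vector("list", length(case_ids))
  unmatched <- character(0)
  for (i in order_cases) {
    d <- abs(ctrl_lp - case_lp[i])
    ok <- which(available & d <= caliper)
    if (length(ok) == 0L) {
      unmatched <- c(unmatched, case_ids[i])
      next
    }
    pick <- ok[order(d[ok])][seq_len(min(ratio, length(ok)))]
    if (!with_replacement) available[pick] <- FALSE
    sets[[i]] <- tibble(
      case_id = case_ids[i],
      control_id = ctrl_ids[pick],
      rank = seq_along(pick),
      distance = d[pick]
    )
  }
  schema <- tibble(case_id = character(), control_id = character(),
                   rank = integer(), distance = numeric())
  matched_sets <- bind_rows(schema, sets)
  if (nrow(matched_sets)) matched_sets <- arrange(matched_sets, .data$case_id,
                                                  .data$rank)

  matched_case_ids <- unique(matched_sets$case_id)
  matched_ids <- c(matched_case_ids, matched_sets$control_id)
  balance <- balance_table(model$subjects, matched_ids,
                           covariates = model$covariates)

  structure(list(
    matched_sets = matched_sets,
    caliper_width = caliper,
    unmatched_cases = sort(unmatched),
    balance = balance,
    ratio = as.integer(ratio),
    caliper_multiplier = caliper_multiplier,
    with_replacement = with_replacement,
    sd_scope = sd_scope,
    seed = as.integer(seed)
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "1:%d nearest-neighbor caliper match (caliper %.4f logit units)\n",
    x$ratio, x$caliper_width
  ))
  cat(sprintf("  matched cases: %d; matched controls: %d; unmatched cases: %d\n",
              length(unique(x$matched_sets$case_id)),
              nrow(x$matched_sets), length(x$unmatched_cases)))
  invisible(x)
}

#' @describeIn match_nearest_neighbor the matched case-control pairs.
#' @param x A `match_result`.
#' @param ... Unused.
#' @export
tidy.match_result <- function(x, ...) x$matched_sets

#' @describeIn match_nearest_neighbor one-row matching summary.
#' @export
glance.match_result <- function(x, ...) {
  tibble(
    n_matched_cases = length(unique(x$matched_sets$case_id)),
    n_matched_controls = nrow(x$matched_sets),
    n_unmatched_cases = length(x$unmatched_cases),
    caliper_width = x$caliper_width,
    ratio = x$ratio
  )
}

#' Standardized difference between two groups
#'
#' For continuous variables,
#' \eqn{d = |\bar x_a - \bar x_b| / \sqrt{(s_a^2 + s_b^2)/2}}; for binary
#' variables, \eqn{d = |p_a - p_b| / \sqrt{(p_a(1-p_a) + p_b(1-p_b))/2}}.
#' Identical group summaries give 0; a zero pooled variance with unequal
#' means gives `Inf`.
#'
#' @param x,y Value vectors for the two groups. For `kind = "binary"`
#'   these may be logical, 0/1 numeric, or two-level factors (the second
#'   level is the event).
#' @param kind `"continuous"` or `"binary"`.
#' @return A single non-negative number (possibly `Inf`).
#' @export
standardized_difference <- function(x, y, kind = c("continuous", "binary")) {
  kind <- arg_match(kind)
  as01 <- function(v) {
    if (is.factor(v)) v <- as.integer(v) - 1L
    as.numeric(v)
  }
  if (kind == "continuous") {
    num <- abs(mean(x) - mean(y))
    den <- sqrt((var(x) + var(y)) / 2)
  } else {
    pa <- mean(as01(x))
    pb <- mean(as01(y))
    num <- abs(pa - pb)
    den <- sqrt((pa * (1 - pa) + pb * (1 - pb)) / 2)
  }
  if (num == 0) return(0)
  if (den == 0) {
    warn("Zero pooled variance with unequal means; standardized difference is infinite.")
    return(Inf)
  }
  num / den
}

#' Covariate balance before and after matching
#'
#' Computes per-covariate group summaries and absolute standardized
#' differences on the full cohort (pre) and on a matched subset (post).
#'
#' @param subjects Subject tibble (`subject_id`, `group`, covariates).
#' @param matched_ids Character vector of subject ids in the matched
#'   cohort, or a `match_result`.
#' @param covariates Covariate names; numeric columns are treated as
#'   continuous, factors/characters/logicals as binary.
#' @return A tibble: `covariate`, `kind`, pre/post group means, `d_pre`,
#'   `d_post`.
#' @export
balance_table <- function(subjects, matched_ids,
                          covariates = c("age", "sex")) {
  if (inherits(matched_ids, "match_result")) {
    m <- matched_ids
    matched_ids <- c(unique(m$matched_sets$case_id), m$matched_sets$control_id)
  }
  post <- filter(subjects, .data$subject_id %in% matched_ids)
  one <- function(dat, v) {
    is_case <- as_case_logical(dat$group)
    col <- dat[[v]]
    if (!any(is_case) || !any(!is_case)) {
      return(list(kind = if (is.numeric(col)) "continuous" else "binary",
                  mean_case = NA_real_, mean_control = NA_real_,
                  d = NA_real_))
    }
    if (is.numeric(col)) {
      list(kind = "continuous",
           mean_case = mean(col[is_case]), mean_control = mean(col[!is_case]),
           d = standardized_difference(col[is_case], col[!is_case],
                                       "continuous"))
    } else {
      x01 <- if (is.factor(col)) as.integer(col) - 1L else
        as.integer(as.factor(col)) - 1L
      list(kind = "binary",
           mean_case = mean(x01[is_case]), mean_control = mean(x01[!is_case]),
           d = standardized_difference(x01[is_case], x01[!is_case], "binary"))
    }
  }
  purrr::map_dfr(covariates, function(v) {
    pre <- one(subjects, v)
    pst <- one(post, v)
    tibble(
      covariate = v, kind = pre$kind,
      pre_case = pre$mean_case, pre_control = pre$mean_control,
      post_case = pst$mean_case, post_control = pst$mean_control,
      d_pre = pre$d, d_post = pst$d
    )
  })
}
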