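# Independent oracles: naive, loop-based reference implementations used to
# validate the package's vectorized code paths.

# Mann-Whitney U by direct pair counting
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Exact two-sided p (doubled smaller tail, capped at 1) by enumerating
# every assignment of the pooled values into groups of size |x| and |y|
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  nn <- length(pooled)
  obs <- oracle_u(x, y)
  idx <- utils::combn(nn, n1)
  stats <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  min(1, 2 * min(mean(stats <= obs + 1e-12), mean(stats >= obs - 1e-12)))
}

# AUC by explicit pairwise comparison
oracle_auc <- function(case, control) {
  oracle_u(case, control) / (length(case) * length(control))
}

# best Youden J over an exhaustive sweep of thresholds (all observed
# values plus midpoints plus sentinels beyond the range)
oracle_best_j <- function(case, control) {
  v <- sort(unique(c(case, control)))
  cands <- unique(c(min(v) - 1, v, (v[-1] + v[-length(v)]) / 2,
                    max(v) + 1))
  best <- -Inf
  for (t in cands) {
    j <- mean(case >= t) + mean(control < t) - 1
    if (j > best) best <- j
  }
  best
}

# greedy nearest-neighbor caliper matching, naive loops; replicates the
# documented algorithm (seeded random case order, nearest-first, id
# tie-break, without replacement)
oracle_match <- function(case_ids, case_lp, ctrl_ids, ctrl_lp,
                         ratio, caliper, seed) {
  o <- order(ctrl_ids)
  ctrl_ids <- ctrl_ids[o]
  ctrl_lp <- ctrl_lp[o]
  used <- rep(FALSE, length(ctrl_ids))
  out <- list()
  order_cases <- withr::with_seed(seed, sample(seq_along(case_ids)))
  for (i in order_cases) {
    picks <- character(0)
    for (r in seq_len(ratio)) {
      best <- NA_integer_
      for (j in seq_along(ctrl_ids)) {
        if (used[j]) next
        d <- abs(ctrl_lp[j] - case_lp[i])
        if (d > caliper) next
        if (is.na(best) || d < abs(ctrl_lp[best] - case_lp[i])) best <- j
      }
      if (is.na(best)) break
      used[best] <- TRUE
      picks <- c(picks, ctrl_ids[best])
    }
    if (length(picks)) {
      out[[case_ids[i]]] <- picks
    }
  }
  out
}

# compare matched-set lists irrespective of case order / empty-name quirks
expect_same_match <- function(got, ref) {
  nm <- function(l) if (is.null(names(l))) character(0) else names(l)
  expect_setequal(nm(got), nm(ref))
  for (nm in names(ref)) expect_equal(unname(got[[nm]]), unname(ref[[nm]]))
  invisible(NULL)
}

# binormal closed-form AUC for a Ct-shift delta with per-group noise sd
closed_form_auc <- function(delta, sigma) pnorm(delta / (sigma * sqrt(2)))

# minimal single-replicate Ct table builder: `mat` is samples x assays
make_ct <- function(mat, roles = NULL) {
  samples <- rownames(mat)
  assays <- colnames(mat)
  if (is.null(roles)) roles <- rep("candidate_marker", length(assays))
  tibble::tibble(
    sample_id = rep(samples, times = length(assays)),
    assay_id = rep(assays, each = length(samples)),
    assay_role = rep(roles, each = length(samples)),
    replicate = 1L,
    ct = as.vector(mat)
  )
}

# hand-built propensity model object for matching tests
make_ps_model <- function(ids, group, logit_ps) {
  subjects <- tibble::tibble(
    subject_id = ids,
    group = factor(group, levels = c("control", "case")),
    age = 0, sex = factor("male", levels = c("female", "male"))
  )
  structure(list(
    scores = tibble::tibble(
      subject_id = ids,
      group = subjects$group,
      ps = stats::plogis(logit_ps),
      logit_ps = logit_ps
    ),
    coefficients = c("(Intercept)" = 0),
    c_statistic = 0.5,
    method = "ml",
    covariates = "age",
    subjects = subjects
  ), class = "ps_model")
}
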