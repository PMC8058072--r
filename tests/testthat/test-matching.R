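# Propensity model, greedy caliper matching, standardized differences.

make_subjects <- function(age_control, age_case, sex = NULL) {
  n <- length(age_control) + length(age_case)
  if (is.null(sex)) sex <- rep("male", n)
  tibble::tibble(
    subject_id = sprintf("P%02d", seq_len(n)),
    group = factor(rep(c("control", "case"),
                       c(length(age_control), length(age_case))),
                   levels = c("control", "case")),
    age = c(age_control, age_case),
    sex = factor(sex, levels = c("female", "male"))
  )
}

test_that("constant covariates collapse to the intercept-only model", {
  s <- make_subjects(rep(50, 8), rep(50, 4))
  expect_warning(m <- fit_propensity(s, c("age", "sex")), "constant")
  expect_equal(unique(round(m$scores$ps, 10)), 1 / 3)
  expect_equal(m$c_statistic, 0.5)
})

test_that("a perfectly separating covariate triggers the Firth fallback", {
  s <- make_subjects(seq(40, 54, 2), seq(70, 76, 2))
  expect_warning(m <- fit_propensity(s, "age"), "Separation")
  expect_equal(m$method, "firth")
  expect_gt(m$c_statistic, 0.99)
  expect_true(all(m$scores$ps > 0 & m$scores$ps < 1))
})

test_that("ML coefficients match a direct likelihood-maximization oracle", {
  # overlapping ages so the MLE exists and is finite
  s <- make_subjects(c(50, 60, 70, 55), c(58, 68, 80, 72))
  m <- fit_propensity(s, "age")
  expect_equal(m$method, "ml")

  negll <- function(b) {
    eta <- b[1] + b[2] * s$age
    y <- as.numeric(s$group == "case")
    -sum(y * eta - log1p(exp(eta)))
  }
  oracle <- stats::optim(c(0, 0), negll, method = "BFGS")$par
  expect_equal(unname(m$coefficients), oracle, tolerance = 1e-3)

  # c-statistic equals the rank AUC of ps against labels
  is_case <- s$group == "case"
  expect_equal(
    m$c_statistic,
    roc_auc(m$scores$ps[is_case], m$scores$ps[!is_case],
            ci_method = "none")$auc
  )
})

test_that("the C-statistic is invariant under monotone transforms of the score", {
  set.seed(14)
  for (i in 1:20) {
    ps <- runif(30)
    lab <- rep(c(TRUE, FALSE), c(10, 20))
    a <- roc_auc(ps[lab], ps[!lab], ci_method = "none")$auc
    f <- function(p) plogis(3 * qlogis(p) + 1) # strictly monotone
    expect_equal(roc_auc(f(ps[lab]), f(ps[!lab]), ci_method = "none")$auc,
                 a, tolerance = 1e-12)
  }
})

test_that("hand-built example matches the documented greedy rule", {
  m <- make_ps_model(
    ids = c("case1", "ctrlA", "ctrlB", "ctrlC"),
    group = c("case", "control", "control", "control"),
    logit_ps = c(0.0, 0.01, 0.02, 0.5)
  )
  sdl <- sd(m$scores$logit_ps)
  res <- match_nearest_neighbor(m, ratio = 4,
                                caliper_multiplier = 0.1 / sdl, seed = 1)
  expect_equal(res$caliper_width, 0.1, tolerance = 1e-12)
  expect_setequal(res$matched_sets$control_id, c("ctrlA", "ctrlB"))
  expect_equal(res$matched_sets$control_id[res$matched_sets$rank == 1],
               "ctrlA")
  expect_length(res$unmatched_cases, 0)
})

test_that("caliper exclusion leaves every case unmatched", {
  m <- make_ps_model(
    ids = c("c1", "c2", "k1", "k2"),
    group = c("case", "case", "control", "control"),
    logit_ps = c(0, 0.1, 5, 6)
  )
  res <- match_nearest_neighbor(m, ratio = 2, caliper_multiplier = 0.01,
                                seed = 2)
  expect_equal(nrow(res$matched_sets), 0)
  expect_setequal(res$unmatched_cases, c("c1", "c2"))
})

test_that("abundant in-caliper controls give exactly ratio controls per case, no reuse", {
  set.seed(15)
  n_case <- 20
  n_ctrl <- 200
  ids <- c(sprintf("case%02d", 1:n_case), sprintf("ctrl%03d", 1:n_ctrl))
  lp <- c(rnorm(n_case, 0, 0.05), rnorm(n_ctrl, 0, 0.05))
  m <- make_ps_model(ids, rep(c("case", "control"), c(n_case, n_ctrl)), lp)
  res <- match_nearest_neighbor(m, ratio = 4, caliper_multiplier = 20,
                                seed = 3)
  counts <- table(res$matched_sets$case_id)
  expect_true(all(counts == 4))
  expect_false(anyDuplicated(res$matched_sets$control_id) > 0)
  expect_lte(nrow(res$matched_sets), 4 * n_case)
})

test_that("every matched pair satisfies the caliper bound", {
  set.seed(16)
  for (i in 1:300) {
    n_case <- sample(2:6, 1)
    n_ctrl <- sample(4:14, 1)
    ids <- sprintf("s%02d", seq_len(n_case + n_ctrl))
    lp <- rnorm(n_case + n_ctrl)
    m <- make_ps_model(ids, rep(c("case", "control"), c(n_case, n_ctrl)), lp)
    res <- match_nearest_neighbor(m, ratio = sample(1:4, 1),
                                  caliper_multiplier = runif(1, 0.05, 1),
                                  seed = i)
    if (nrow(res$matched_sets) == 0) next
    lp_by_id <- stats::setNames(lp, ids)
    gap <- abs(lp_by_id[res$matched_sets$case_id] -
                 lp_by_id[res$matched_sets$control_id])
    expect_true(all(gap <= res$caliper_width + 1e-12))
  }
})

test_that("matching equals the naive greedy oracle on small instances", {
  set.seed(17)
  for (i in 1:200) {
    n_case <- sample(1:4, 1)
    n_ctrl <- sample(2:8, 1) # total <= 12
    ids <- sprintf("s%02d", seq_len(n_case + n_ctrl))
    group <- rep(c("case", "control"), c(n_case, n_ctrl))
    lp <- round(rnorm(n_case + n_ctrl), 2)
    ratio <- sample(1:3, 1)
    mult <- runif(1, 0.2, 2)
    m <- make_ps_model(ids, group, lp)
    res <- match_nearest_neighbor(m, ratio = ratio,
                                  caliper_multiplier = mult, seed = i)
    ref <- oracle_match(
      case_ids = ids[group == "case"], case_lp = lp[group == "case"],
      ctrl_ids = ids[group == "control"], ctrl_lp = lp[group == "control"],
      ratio = ratio, caliper = mult * sd(lp), seed = i
    )
    got <- split(res$matched_sets$control_id, res$matched_sets$case_id)
    expect_same_match(got, ref)
  }
})

test_that("matching reduces covariate imbalance in expectation", {
  pre_d <- post_d <- numeric(100)
  for (s in 1:100) {
    cfg <- simulation_config(n_control = 100, n_case = 25,
                             age_shift_case = 6, replicate_count = 1,
                             seed = 1000 + s)
    subj <- simulate_cohort(cfg)$subjects
    ps <- suppressWarnings(fit_propensity(subj, c("age", "sex")))
    res <- match_nearest_neighbor(ps, ratio = 2, seed = s)
    age_row <- res$balance[res$balance$covariate == "age", ]
    pre_d[s] <- age_row$d_pre
    post_d[s] <- age_row$d_post
  }
  expect_lt(mean(post_d), mean(pre_d))
})

test_that("standardized differences follow the pooled-variance formula", {
  expect_equal(standardized_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(
    standardized_difference(c(-1, 0, 1), c(0, 1, 2), "continuous"), 1.0
  )
  expect_equal(
    standardized_difference(c(TRUE, FALSE), c(FALSE, TRUE), "binary"), 0
  )
  expect_warning(
    d <- standardized_difference(c(1, 1), c(2, 2), "continuous"),
    "infinite"
  )
  expect_identical(d, Inf)
})
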