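# Rank statistics: Mann-Whitney, ROC/AUC, Youden cutoff, Spearman,
# categorical tests, bootstrap CI.

test_that("mann_whitney reproduces exact enumeration results", {
  r1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$p_value, 0.1)
  expect_equal(r1$statistic, 0)

  # identical multisets: U = n^2/2, p = 1
  r2 <- mann_whitney(c(1, 5, 9), c(1, 5, 9))
  expect_equal(r2$statistic, 9 / 2)
  expect_equal(r2$p_value, 1)

  # tied input, enumeration with midranks
  x <- c(1, 2, 2, 3)
  y <- c(2, 3, 4, 5)
  r3 <- mann_whitney(x, y)
  expect_equal(r3$statistic, oracle_u(x, y))
  expect_equal(r3$p_value, oracle_mw_p(x, y))

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p matches full enumeration for all tie-free sizes up to 10", {
  set.seed(11)
  for (n1 in 1:5) {
    for (n2 in n1:(10 - n1)) {
      for (rep in 1:3) {
        v <- sample(seq_len(50), n1 + n2) # distinct => tie-free
        x <- v[seq_len(n1)]
        y <- v[-seq_len(n1)]
        got <- mann_whitney(x, y)
        expect_equal(got$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
        expect_equal(got$statistic, oracle_u(x, y))
      }
    }
  }
})

test_that("large-sample Mann-Whitney p agrees with the tie-corrected normal approximation", {
  set.seed(21)
  for (i in 1:20) {
    x <- round(rnorm(15, 0, 2), 1)
    y <- round(rnorm(18, 0.5, 2), 1)
    got <- mann_whitney(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    )
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("roc_auc handles separation, ties and the pairwise definition", {
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3), B = 200)$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3), B = 200)$auc, 0.5)
  expect_equal(roc_auc(c(3, 5), c(1, 4), B = 200)$auc, 0.75)
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")
})

test_that("AUC equals U/(n1 n2) on random instances", {
  set.seed(31)
  for (i in 1:1000) {
    n1 <- sample(2:12, 1)
    n2 <- sample(2:12, 1)
    case <- sample(seq_len(8), n1, replace = TRUE) # ties likely
    control <- sample(seq_len(8), n2, replace = TRUE)
    a <- roc_auc(case, control, ci_method = "none")$auc
    u <- mann_whitney(case, control, exact_max = 0L)$statistic
    expect_equal(a, u / (n1 * n2), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and complements under label swap", {
  set.seed(41)
  for (i in 1:50) {
    case <- rnorm(12, 1)
    control <- rnorm(15)
    a <- roc_auc(case, control, ci_method = "none")$auc
    expect_equal(roc_auc(exp(case), exp(control), ci_method = "none")$auc,
                 a, tolerance = 1e-12)
    expect_equal(roc_auc(control, case, ci_method = "none")$auc, 1 - a,
                 tolerance = 1e-12)
  }
})

test_that("roc_auc confidence intervals bracket the point estimate and are seed-stable", {
  case <- c(2.1, 3.0, 3.5, 4.2, 5.0)
  control <- c(1.0, 1.8, 2.5, 2.9, 3.2)
  r1 <- roc_auc(case, control, B = 500, seed = 9)
  r2 <- roc_auc(case, control, B = 500, seed = 9)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_identical(r1$ci_high, r2$ci_high)
  expect_lte(r1$ci_low, r1$auc)
  expect_gte(r1$ci_high, r1$auc)
  rh <- roc_auc(case, control, ci_method = "hanley")
  expect_lte(rh$ci_low, rh$auc)
  expect_gte(rh$ci_high, rh$auc)
})

test_that("optimal_cutoff maximizes Youden J with the documented tie rules", {
  # perfect separation
  r <- optimal_cutoff(c(5, 6), c(1, 2))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # degenerate: all scores equal -> sens 1, spec 0
  r0 <- optimal_cutoff(c(2, 2), c(2, 2, 2))
  expect_equal(r0$youden_j, 0)
  expect_equal(r0$sensitivity, 1)
  expect_equal(r0$specificity, 0)

  # J-tie broken toward higher sensitivity, then lower cutoff
  r1 <- optimal_cutoff(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r1$sensitivity, 1)
  expect_equal(r1$cutoff, 1.5)
  expect_equal(r1$youden_j, 1 / 3)
})

test_that("no threshold beats the Youden cutoff in an exhaustive sweep", {
  set.seed(51)
  for (i in 1:300) {
    case <- sample(seq_len(10), sample(2:8, 1), replace = TRUE)
    control <- sample(seq_len(10), sample(2:8, 1), replace = TRUE)
    got <- optimal_cutoff(case, control)
    expect_gte(got$youden_j + 1e-12, oracle_best_j(case, control))
    # reported sens/spec are attained at the reported cutoff
    expect_equal(got$sensitivity, mean(case >= got$cutoff))
    expect_equal(got$specificity, mean(control < got$cutoff))
  }
})

test_that("spearman_cor matches the rank formula and base R", {
  expect_equal(spearman_cor(1:6, (1:6)^3)$r, 1)
  expect_equal(spearman_cor(1:6, -(1:6))$r, -1)
  expect_equal(spearman_cor(1:4, c(1, 3, 2, 4))$r, 0.8)
  set.seed(61)
  for (i in 1:20) {
    x <- sample(1:10, 12, replace = TRUE)
    y <- sample(1:10, 12, replace = TRUE)
    got <- spearman_cor(x, y)
    expect_equal(got$r, stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_warning(out <- spearman_cor(c(1, 1, 1), c(1, 2, 3)),
                 "rank variance")
  expect_true(is.na(out$r))
})

test_that("categorical_test applies Fisher or chi-square by expected counts", {
  # sex distribution of the matched cohort: 15/150 vs 4/43 female
  sex_tab <- matrix(c(15, 4, 135, 39), nrow = 2)
  got <- categorical_test(sex_tab)
  expect_equal(got$method, "fisher_exact")
  expect_equal(got$p_value, stats::fisher.test(sex_tab)$p.value)
  expect_equal(round(got$p_value, 3), 1.000)

  # extreme diagonal table: exact p = 2 / C(20, 10)
  got2 <- categorical_test(matrix(c(10, 0, 0, 10), nrow = 2))
  expect_equal(got2$method, "fisher_exact")
  expect_equal(got2$p_value, 2 / choose(20, 10), tolerance = 1e-9)

  # balanced table with no association
  got3 <- categorical_test(matrix(c(50, 50, 50, 50), nrow = 2))
  expect_equal(got3$method, "pearson_chisq")
  expect_equal(got3$p_value, 1.0)

  expect_error(categorical_test(matrix(0, 2, 2)), "at least one")
  expect_error(categorical_test(matrix(c(1, 2, 3, -1), 2)), "non-negative")
})

test_that("bootstrap_ci is seeded, degenerate-safe and monotone in level", {
  x <- rnorm(40)
  r1 <- bootstrap_ci(x, mean, B = 200, seed = 5)
  r2 <- bootstrap_ci(x, mean, B = 200, seed = 5)
  expect_identical(r1$lower, r2$lower)
  expect_identical(r1$upper, r2$upper)

  # constant statistic -> zero-width interval
  rc <- bootstrap_ci(x, function(d) 42, B = 100, seed = 1)
  expect_equal(rc$lower, 42)
  expect_equal(rc$upper, 42)

  # nested levels
  r90 <- bootstrap_ci(x, mean, B = 400, level = 0.90, seed = 7)
  r99 <- bootstrap_ci(x, mean, B = 400, level = 0.99, seed = 7)
  expect_lte(r99$lower, r90$lower)
  expect_gte(r99$upper, r90$upper)

  expect_error(bootstrap_ci(x, mean, B = 50), "at least 100")
})

test_that("stratified bootstrap redraws resamples on which the statistic is undefined", {
  d <- data.frame(g = rep(c("a", "b"), c(5, 5)), v = 1:10)
  stat <- function(dd) {
    # undefined unless both strata present (always true when stratified)
    if (length(unique(dd$g)) < 2) return(NA_real_)
    mean(dd$v[dd$g == "a"]) - mean(dd$v[dd$g == "b"])
  }
  r <- bootstrap_ci(d, stat, B = 100, strata = d$g, seed = 3)
  expect_equal(r$n_redrawn, 0L)
  expect_true(r$lower <= r$upper)
})
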