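# End-to-end study pipeline: cohort assembly (simulate or read), PS
# matching, quality exclusion, discovery/training-test split, qPCR
# normalization, discovery screening, and cross-validated diagnostic
# evaluation with per-marker qualification reports.

#' Study configuration
#'
#' Bundles every pipeline parameter. By default the cohort is simulated at
#' enrollment scale (299 controls, 44 cases) so that 1:4 propensity-score
#' matching and a ~9.4% quality-exclusion rate yield an analysis cohort of
#' roughly 150 controls and 43 cases, which is then split 6/3 into the
#' discovery cohort and the remainder into the training/test cohort.
#'
#' All randomness flows from the single root `seed`: stage i uses
#' `seed + i` (simulate +1, matching order +2, quality exclusion +3,
#' split +4, evaluation +5), so each stage is independently reproducible.
#'
#' @param simulation A [simulation_config()] for synthetic input, or `NULL`
#'   when reading files.
#' @param subjects_file,ct_file CSV paths (as written by
#'   [write_subjects_csv()] / [write_ct_csv()]) used when `simulation` is
#'   `NULL`.
#' @param n_discovery_control,n_discovery_case Discovery-cohort group sizes
#'   (default 6 and 3); must be strictly smaller than the post-exclusion
#'   group counts.
#' @param match_ratio,caliper_multiplier Matching parameters (1:4 within
#'   0.2 x SD of the logit PS by default).
#' @param covariates Propensity-model covariates (default age and sex).
#' @param poor_quality_rate Sample quality-failure rate; defaults to the
#'   simulation config's value (or 0 for file input).
#' @param n_internal_controls Number of reference assays selected by
#'   global-mean stability.
#' @param discordance_limit Replicate discordance flag threshold (cycles).
#' @param fc_threshold,alpha Screening thresholds (fold change > 2, raw
#'   p < 0.05 by default).
#' @param fc_center `"mean"` (conventional fold change, default) or
#'   `"median"` (robust to the heavy tails of log-normal expression).
#' @param min_detect_rate Stability (detection-rate) threshold, default 0.8.
#' @param k,n_boot Evaluation parameters: folds (default 5) and bootstrap
#'   resamples (default 1000).
#' @param seed Root seed (mandatory).
#' @return A list of class `study_config`.
#' @export
study_config <- function(simulation = simulation_config(n_control = 299L,
                                                        n_case = 44L),
                         subjects_file = NULL,
                         ct_file = NULL,
                         n_discovery_control = 6L,
                         n_discovery_case = 3L,
                         match_ratio = 4L,
                         caliper_multiplier = 0.2,
                         covariates = c("age", "sex"),
                         poor_quality_rate = NULL,
                         n_internal_controls = 2L,
                         discordance_limit = 1.0,
                         fc_threshold = 2.0,
                         alpha = 0.05,
                         fc_center = c("mean", "median"),
                         min_detect_rate = 0.8,
                         k = 5L,
                         n_boot = 1000L,
                         seed = 1L) {
  if (is.null(simulation) && (is.null(subjects_file) || is.null(ct_file))) {
    abort("Provide either `simulation` or both `subjects_file` and `ct_file`.",
          class = "uromir_config_error")
  }
  if (is.null(poor_quality_rate)) {
    poor_quality_rate <- if (is.null(simulation)) 0 else
      simulation$poor_quality_rate
  }
  if (n_discovery_control < 1 || n_discovery_case < 1) {
    abort("Discovery counts must be >= 1.", class = "uromir_config_error")
  }
  structure(list(
    simulation = simulation,
    subjects_file = subjects_file, ct_file = ct_file,
    n_discovery_control = as.integer(n_discovery_control),
    n_discovery_case = as.integer(n_discovery_case),
    match_ratio = as.integer(match_ratio),
    caliper_multiplier = caliper_multiplier,
    covariates = covariates,
    poor_quality_rate = poor_quality_rate,
    n_internal_controls = as.integer(n_internal_controls),
    discordance_limit = discordance_limit,
    fc_threshold = fc_threshold,
    alpha = alpha,
    fc_center = arg_match(fc_center),
    min_detect_rate = min_detect_rate,
    k = as.integer(k),
    n_boot = as.integer(n_boot),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Randomly split a cohort into discovery and training/test sets
#'
#' Draws the requested number of controls and cases (seeded) into the
#' discovery cohort; all remaining subjects form the training/test cohort.
#' The two sets are disjoint and exhaustive.
#'
#' @param subjects Subject tibble.
#' @param n_discovery_control,n_discovery_case Discovery group sizes.
#' @param seed Integer seed.
#' @return `subjects` with an added `cohort` column
#'   (`"discovery"`/`"training_test"`).
#' @export
split_cohort <- function(subjects, n_discovery_control, n_discovery_case,
                         seed = 1L) {
  is_case <- as_case_logical(subjects$group)
  if (sum(!is_case) < n_discovery_control || sum(is_case) < n_discovery_case) {
    abort(sprintf(
      "Cannot draw %d controls and %d cases from %d/%d available.",
      n_discovery_control, n_discovery_case, sum(!is_case), sum(is_case)
    ), class = "uromir_split_error")
  }
  disc <- withr::with_seed(seed, c(
    sample(subjects$subject_id[!is_case], n_discovery_control),
    sample(subjects$subject_id[is_case], n_discovery_case)
  ))
  mutate(subjects, cohort = ifelse(.data$subject_id %in% disc,
                                   "discovery", "training_test"))
}

#' Run the full biomarker-qualification pipeline
#'
#' Executes, in order: cohort simulation (or file input), propensity-score
#' matching on age and sex, quality exclusion, discovery/training-test
#' split, replicate aggregation, internal-control selection, 2^-dCt
#' normalization, discovery screening, and per-marker evaluation in the
#' training/test cohort (Mann-Whitney tests, medians, 5-fold
#' cross-validated AUCs with bootstrap CIs for all-stage and stage-I
#' strata, Youden cutoffs, and Spearman correlation with TNM stage among
#' cases). A marker is *qualified* when it passes the discovery screen and
#' remains significant (p < alpha) in the training/test cohort.
#'
#' @param config A [study_config()].
#' @return An object of class `uromir_study`; see the fields in the
#'   returned list, and [write_study()] for file output. The same inputs
#'   (config including seed) always give an identical result document.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "study_config")) {
    abort("`config` must be created by study_config().")
  }
  seed <- config$seed
  log <- character(0)
  note <- function(stage, msg) {
    log <<- c(log, sprintf("[%s] %s", stage, msg))
  }

  # --- input -----------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- seed + 1L
    cohort <- simulate_cohort(sim_cfg)
    subjects <- cohort$subjects
    ct <- cohort$ct
    note("simulate", sprintf("simulated %d controls / %d cases, seed %d",
                             sim_cfg$n_control, sim_cfg$n_case, sim_cfg$seed))
  } else {
    subjects <- read_subjects_csv(config$subjects_file)
    ct <- read_ct_csv(config$ct_file)
    note("input", sprintf("read %d subjects, %d Ct rows",
                          nrow(subjects), nrow(ct)))
  }

  # --- propensity-score matching --------------------------------------
  ps <- fit_propensity(subjects, config$covariates)
  match <- match_nearest_neighbor(
    ps, ratio = config$match_ratio,
    caliper_multiplier = config$caliper_multiplier,
    seed = seed + 2L
  )
  matched_ids <- c(unique(match$matched_sets$case_id),
                   match$matched_sets$control_id)
  subjects_matched <- filter(subjects, .data$subject_id %in% matched_ids)
  ct_matched <- filter(ct, .data$sample_id %in% matched_ids)
  note("match", sprintf(
    "C-statistic %.3f; matched %d cases to %d controls (caliper %.4f)",
    ps$c_statistic, length(unique(match$matched_sets$case_id)),
    nrow(match$matched_sets), match$caliper_width
  ))

  # --- quality exclusion ----------------------------------------------
  qf <- apply_quality_failures(ct_matched, config$poor_quality_rate,
                               seed = seed + 3L)
  analysis_subjects <- filter(subjects_matched,
                              !.data$subject_id %in% qf$excluded)
  note("quality", sprintf("excluded %d poor-quality samples",
                          length(qf$excluded)))

  # --- discovery / training-test split --------------------------------
  analysis_subjects <- split_cohort(
    analysis_subjects, config$n_discovery_control, config$n_discovery_case,
    seed = seed + 4L
  )
  disc_ids <- analysis_subjects$subject_id[
    analysis_subjects$cohort == "discovery"]
  tt_ids <- analysis_subjects$subject_id[
    analysis_subjects$cohort == "training_test"]
  note("split", sprintf("discovery %d, training/test %d",
                        length(disc_ids), length(tt_ids)))

  # --- normalization ---------------------------------------------------
  ct_agg <- aggregate_replicates(qf$ct, config$discordance_limit)
  refs <- select_internal_controls(ct_agg, config$n_internal_controls)
  expr <- delta_ct(ct_agg, refs)
  note("normalize", sprintf("internal controls: %s",
                            paste(refs, collapse = ", ")))

  # --- discovery screening --------------------------------------------
  expr_disc <- filter(expr, .data$sample_id %in% disc_ids)
  screen <- differential_screen(
    expr_disc, analysis_subjects,
    fc_threshold = config$fc_threshold, alpha = config$alpha,
    center = config$fc_center
  )
  screen <- mutate(screen,
                   stable = .data$detect_rate_case >= config$min_detect_rate &
                     .data$detect_rate_control >= config$min_detect_rate)
  candidates <- screen$marker_id[screen$selected & screen$stable]
  note("screen", sprintf("%d of %d markers selected in discovery",
                         length(candidates), nrow(screen)))

  # --- evaluation on the training/test cohort -------------------------
  expr_tt <- filter(expr, .data$sample_id %in% tt_ids)
  subj_tt <- filter(analysis_subjects, .data$subject_id %in% tt_ids)
  stage1_ids <- subj_tt$subject_id[
    !is.na(subj_tt$tnm_stage) & subj_tt$tnm_stage == "I"]
  control_ids <- subj_tt$subject_id[subj_tt$group == "control"]

  eval_schema <- tibble(
    marker_id = character(), median_control = numeric(),
    median_case = numeric(), p_value = numeric(), auc = numeric(),
    auc_ci_low = numeric(), auc_ci_high = numeric(), cutoff = numeric(),
    sensitivity = numeric(), specificity = numeric(),
    mean_train_auc = numeric(), train_ci_low = numeric(),
    train_ci_high = numeric(), mean_test_auc = numeric(),
    test_ci_low = numeric(), test_ci_high = numeric(),
    stage1_mean_train_auc = numeric(), stage1_mean_test_auc = numeric(),
    stage_corr_r = numeric(), stage_corr_p = numeric(),
    qualified = logical(), cv = list(), cv_stage1 = list()
  )
  evaluation <- purrr::map_dfr(candidates, function(m) {
    d <- filter(expr_tt, .data$marker_id == m) %>%
      left_join(select(subj_tt, sample_id = "subject_id", "group",
                       "tnm_stage"),
                by = "sample_id") %>%
      filter(!is.na(.data$rel_expr))
    is_case <- as_case_logical(d$group)
    mw <- mann_whitney(d$rel_expr[is_case], d$rel_expr[!is_case])
    roc <- roc_auc(d$rel_expr[is_case], d$rel_expr[!is_case],
                   seed = seed + 5L)
    cv_all <- kfold_cross_validate(d$rel_expr, is_case, k = config$k,
                                   B = config$n_boot, seed = seed + 5L)
    # stage-I stratum: full control group vs stage-I cases only
    d1 <- filter(d, !is_case | (!is.na(.data$tnm_stage) &
                                  .data$tnm_stage == "I"))
    is_case1 <- as_case_logical(d1$group)
    cv_stage1 <- if (sum(is_case1) >= config$k) {
      kfold_cross_validate(d1$rel_expr, is_case1, k = config$k,
                           B = config$n_boot, seed = seed + 5L)
    } else NULL
    corr <- stage_correlation(expr_tt, subj_tt, m)
    tibble(
      marker_id = m,
      median_control = median(d$rel_expr[!is_case]),
      median_case = median(d$rel_expr[is_case]),
      p_value = mw$p_value,
      auc = roc$auc,
      auc_ci_low = roc$ci_low, auc_ci_high = roc$ci_high,
      cutoff = roc$cutoff,
      sensitivity = roc$sensitivity, specificity = roc$specificity,
      mean_train_auc = cv_all$mean_train_auc,
      train_ci_low = cv_all$boot_ci_train[1],
      train_ci_high = cv_all$boot_ci_train[2],
      mean_test_auc = cv_all$mean_test_auc,
      test_ci_low = cv_all$boot_ci_test[1],
      test_ci_high = cv_all$boot_ci_test[2],
      stage1_mean_train_auc = if (is.null(cv_stage1)) NA_real_ else
        cv_stage1$mean_train_auc,
      stage1_mean_test_auc = if (is.null(cv_stage1)) NA_real_ else
        cv_stage1$mean_test_auc,
      stage_corr_r = corr$r,
      stage_corr_p = corr$p_value,
      qualified = mw$p_value < config$alpha,
      cv = list(cv_all),
      cv_stage1 = list(cv_stage1)
    )
  })
  evaluation <- bind_rows(eval_schema, evaluation)
  qualified <- evaluation$marker_id[evaluation$qualified]
  note("evaluate", sprintf("%d qualified marker(s): %s",
                           length(qualified),
                           paste(qualified, collapse = ", ")))

  structure(list(
    config = config,
    subjects = subjects,
    ps_model = ps,
    match = match,
    excluded_samples = qf$excluded,
    analysis_subjects = analysis_subjects,
    reference_assays = refs,
    expression = expr,
    screen = screen,
    candidates = candidates,
    evaluation = evaluation,
    qualified = qualified,
    characteristics = characteristics_table(
      filter(analysis_subjects, .data$cohort == "training_test")),
    log = log
  ), class = "uromir_study")
}

#' @export
print.uromir_study <- function(x, ...) {
  cat("Urinary miRNA biomarker qualification study\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Spearman correlation of a marker's expression with TNM stage
#'
#' Cases only; stage is treated as ordinal 1-4.
#'
#' @param expr Expression tibble.
#' @param subjects Subject tibble with `tnm_stage`.
#' @param marker Marker id.
#' @return A one-row tibble from [spearman_cor()].
#' @export
stage_correlation <- function(expr, subjects, marker) {
  d <- filter(expr, .data$marker_id == marker) %>%
    left_join(select(subjects, sample_id = "subject_id", "group",
                     "tnm_stage"),
              by = "sample_id") %>%
    filter(as_case_logical(.data$group), !is.na(.data$tnm_stage),
           !is.na(.data$rel_expr))
  stage_num <- match(d$tnm_stage, c("I", "II", "III", "IV"))
  spearman_cor(d$rel_expr, stage_num)
}

#' Cohort-characteristics summary table
#'
#' Per-covariate group summaries in the style of a clinical Table 1:
#' median [IQR] with a Mann-Whitney p-value and standardized difference
#' for continuous covariates; counts (%) with a Fisher/chi-square p-value
#' and binary standardized difference for sex; stage and T-stage
#' distributions among cases.
#'
#' @param subjects Subject tibble.
#' @return A tibble: `variable`, `control`, `case`, `p_value`, `d`.
#' @export
characteristics_table <- function(subjects) {
  is_case <- as_case_logical(subjects$group)
  med_iqr <- function(v) {
    sprintf("%.2f [%.2f-%.2f]", median(v), quantile(v, 0.25),
            quantile(v, 0.75))
  }
  rows <- list()
  for (v in intersect(c("age", "serum_creatinine"), names(subjects))) {
    x <- subjects[[v]][is_case]
    y <- subjects[[v]][!is_case]
    rows[[v]] <- tibble(
      variable = v, control = med_iqr(y), case = med_iqr(x),
      p_value = mann_whitney(x, y)$p_value,
      d = standardized_difference(x, y, "continuous")
    )
  }
  if ("sex" %in% names(subjects)) {
    tab <- table(factor(subjects$sex, levels = c("female", "male")),
                 factor(is_case, levels = c(FALSE, TRUE)))
    rows$sex <- tibble(
      variable = "sex (female)",
      control = sprintf("%d (%.1f%%)", tab["female", "FALSE"],
                        100 * tab["female", "FALSE"] / sum(!is_case)),
      case = sprintf("%d (%.1f%%)", tab["female", "TRUE"],
                     100 * tab["female", "TRUE"] / sum(is_case)),
      p_value = categorical_test(unclass(tab))$p_value,
      d = standardized_difference(subjects$sex[is_case] == "female",
                                  subjects$sex[!is_case] == "female",
                                  "binary")
    )
  }
  if ("tnm_stage" %in% names(subjects)) {
    st <- table(factor(subjects$tnm_stage[is_case],
                       levels = c("I", "II", "III", "IV")))
    rows$stage <- purrr::map_dfr(names(st), function(s) {
      tibble(variable = paste0("TNM stage ", s), control = "",
             case = sprintf("%d (%.1f%%)", st[[s]],
                            100 * st[[s]] / sum(is_case)),
             p_value = NA_real_, d = NA_real_)
    })
  }
  bind_rows(rows)
}

#' Write the study result document to disk
#'
#' Writes the screen, evaluation, balance and characteristics tables as
#' CSV plus a JSON results document (config echo, internal controls,
#' qualified markers, per-stage log).
#'
#' @param study A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    screen = file.path(dir, "screen.csv"),
    evaluation = file.path(dir, "evaluation.csv"),
    balance = file.path(dir, "balance.csv"),
    characteristics = file.path(dir, "characteristics.csv"),
    results = file.path(dir, "results.json")
  )
  readr::write_csv(study$screen, paths[["screen"]])
  eval_flat <- select(study$evaluation, -dplyr::any_of(c("cv", "cv_stage1")))
  readr::write_csv(eval_flat, paths[["evaluation"]])
  readr::write_csv(study$match$balance, paths[["balance"]])
  readr::write_csv(study$characteristics, paths[["characteristics"]])
  doc <- list(
    seed = study$config$seed,
    c_statistic = study$ps_model$c_statistic,
    caliper_width = study$match$caliper_width,
    n_excluded = length(study$excluded_samples),
    reference_assays = study$reference_assays,
    candidates = study$candidates,
    qualified = study$qualified,
    evaluation = eval_flat,
    log = study$log
  )
  jsonlite::write_json(doc, paths[["results"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
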