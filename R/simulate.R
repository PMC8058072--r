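# Synthetic case-control cohort generator. Produces subject tables and
# long-format qPCR Ct matrices with a known ground truth, so that matching,
# normalization, screening and evaluation are all testable without access
# to patient data.
#
# Noise model: Ct values are Gaussian in the cycle domain, i.e. relative
# expression 2^-dCt is log2-normal. A case-control shift of delta cycles on
# a marker with per-group noise SD sigma yields a closed-form AUC of
# Phi(delta / (sigma * sqrt(2))), which the test suite uses as an oracle.

#' Default candidate-marker panel
#'
#' Eight urinary miRNA assays whose case-control Ct shifts are sized to
#' produce training AUCs spanning roughly 0.5-0.8, the regime of a
#' realistic discovery panel in which some candidates qualify and others
#' fail. Shifts are derived from the binormal identity
#' `delta = sqrt(2) * noise_sd * qnorm(auc)`.
#'
#' @param noise_sd Per-group Ct noise SD in cycles (default 1.5).
#' @param target_auc Named numeric vector of target single-marker AUCs.
#' @return A tibble with columns `name`, `delta_ct_shift`, `noise_sd`.
#' @export
default_marker_specs <- function(noise_sd = 1.5,
                                 target_auc = c(
                                   "miR-1273f" = 0.79,
                                   "miR-619-5p" = 0.786,
                                   "miR-150-3p" = 0.692,
                                   "miR-4327" = 0.639,
                                   "miR-3135b" = 0.620,
                                   "miR-5585-3p" = 0.56,
                                   "miR-6875-5p" = 0.50,
                                   "miR-345-3p" = 0.50
                                 )) {
  tibble(
    name = names(target_auc),
    delta_ct_shift = sqrt(2) * noise_sd * qnorm(unname(target_auc)),
    noise_sd = noise_sd
  )
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic cohort. Defaults
#' emulate a urinary-miRNA case-control study: 150 healthy controls and 43
#' esophageal-cancer cases with matched age/sex margins (median age ~69,
#' ~10% female), a mostly early-stage tumor mix, two stable internal-control
#' assays, duplicate qPCR reactions, and a ~9.4% rate of poor-quality urine
#' samples.
#'
#' @param n_control,n_case Group sizes (>= 1).
#' @param marker_specs Tibble/data frame with columns `name`,
#'   `delta_ct_shift` (cycles; positive shifts lower case Ct, i.e. raise
#'   case expression) and `noise_sd` (cycles, > 0).
#' @param n_internal_controls Number of stable reference assays to simulate.
#' @param internal_control_sd Between-sample Ct SD of internal-control
#'   assays (cycles).
#' @param stage_probs Length-4 probability vector over TNM stages I-IV
#'   (must sum to 1). Default is the observed mix 16/4/12/11 out of 43.
#' @param stage_corr_marker Optional marker name whose expression is
#'   rank-correlated with stage among cases.
#' @param stage_corr_rho Target Spearman correlation (in `[-1, 1]`) between
#'   that marker's expression and stage; negative values mean lower
#'   expression at higher stage.
#' @param poor_quality_rate Probability in `[0, 1)` that a sample is of
#'   poor miRNA quality (used by [apply_quality_failures()]).
#' @param replicate_count Number of qPCR replicates per reaction (>= 1).
#' @param replicate_sd SD in cycles of the technical jitter added to
#'   replicates beyond the first (default 0.15).
#' @param age_mean,age_sd,age_range Age distribution (truncated normal),
#'   shared by both groups; enrollment restricts to 20-90 years.
#' @param age_shift_case Mean age shift (years) added to cases; default 0
#'   (balanced by design). Set positive to create a deliberate imbalance
#'   that exercises propensity-score matching.
#' @param female_prop Proportion of females in both groups.
#' @param creatinine_meanlog,creatinine_sdlog Log-normal parameters for
#'   serum creatinine (mg/dl).
#' @param baseline_ct Optional named vector of per-assay baseline Ct; by
#'   default baselines are spaced evenly over 24-34 cycles.
#' @param seed Integer seed; generation is a pure function of the
#'   configuration including this seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_control = 150L,
                              n_case = 43L,
                              marker_specs = default_marker_specs(),
                              n_internal_controls = 2L,
                              internal_control_sd = 0.15,
                              stage_probs = c(16, 4, 12, 11) / 43,
                              stage_corr_marker = "miR-4327",
                              stage_corr_rho = -0.435,
                              poor_quality_rate = 0.094,
                              replicate_count = 2L,
                              replicate_sd = 0.15,
                              age_mean = 69,
                              age_sd = 8,
                              age_range = c(20, 90),
                              age_shift_case = 0,
                              female_prop = 0.10,
                              creatinine_meanlog = log(0.84),
                              creatinine_sdlog = 0.13,
                              baseline_ct = NULL,
                              seed = 1L) {
  marker_specs <- as_tibble(marker_specs)
  bad <- function(field, msg) {
    abort(sprintf("Invalid simulation config: `%s` %s.", field, msg),
          class = "uromir_config_error")
  }
  if (!is.numeric(n_control) || n_control < 1) bad("n_control", "must be >= 1")
  if (!is.numeric(n_case) || n_case < 1) bad("n_case", "must be >= 1")
  if (!all(c("name", "delta_ct_shift", "noise_sd") %in% names(marker_specs))) {
    bad("marker_specs", "needs columns name, delta_ct_shift, noise_sd")
  }
  if (anyDuplicated(marker_specs$name)) bad("marker_specs", "has duplicate names")
  if (any(marker_specs$noise_sd <= 0)) bad("marker_specs", "noise_sd must be > 0")
  if (n_internal_controls < 1) bad("n_internal_controls", "must be >= 1")
  if (internal_control_sd <= 0) bad("internal_control_sd", "must be > 0")
  if (length(stage_probs) != 4L || any(stage_probs < 0) ||
      abs(sum(stage_probs) - 1) > 1e-9) {
    bad("stage_probs", "must be 4 non-negative probabilities summing to 1")
  }
  if (!is.null(stage_corr_marker) &&
      !stage_corr_marker %in% marker_specs$name) {
    if (missing(stage_corr_marker)) {
      # the default coupling only applies to the default panel
      stage_corr_marker <- NULL
      stage_corr_rho <- NULL
    } else {
      bad("stage_corr_marker", "must name a marker in marker_specs")
    }
  }
  if (!is.null(stage_corr_rho) &&
      (stage_corr_rho < -1 || stage_corr_rho > 1)) {
    bad("stage_corr_rho", "must lie in [-1, 1]")
  }
  if (poor_quality_rate < 0 || poor_quality_rate >= 1) {
    bad("poor_quality_rate", "must lie in [0, 1)")
  }
  if (replicate_count < 1) bad("replicate_count", "must be >= 1")
  if (age_sd <= 0) bad("age_sd", "must be > 0")
  if (female_prop < 0 || female_prop > 1) bad("female_prop", "must be in [0, 1]")

  structure(list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    marker_specs = marker_specs,
    n_internal_controls = as.integer(n_internal_controls),
    internal_control_sd = internal_control_sd,
    stage_probs = stage_probs,
    stage_corr_marker = stage_corr_marker,
    stage_corr_rho = stage_corr_rho,
    poor_quality_rate = poor_quality_rate,
    replicate_count = as.integer(replicate_count),
    replicate_sd = replicate_sd,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    age_shift_case = age_shift_case,
    female_prop = female_prop,
    creatinine_meanlog = creatinine_meanlog,
    creatinine_sdlog = creatinine_sdlog,
    baseline_ct = baseline_ct,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a case-control cohort with qPCR Ct values
#'
#' Generates a subject table (demographics, group, tumor descriptors) and a
#' long-format Ct matrix (sample x assay x replicate) according to a
#' [simulation_config()]. Case samples have each marker's Ct lowered by its
#' `delta_ct_shift` (lower Ct = higher expression); internal-control assays
#' vary only by `internal_control_sd`. When a stage-correlated marker is
#' requested, its case Ct noise is coupled to the latent stage variable
#' through a Gaussian copula so that the marker's expression attains
#' (approximately) the requested Spearman correlation with stage while the
#' Ct marginal is preserved.
#'
#' @param config A [simulation_config()].
#' @return A list of class `cohort_sim` with elements
#'   \describe{
#'     \item{subjects}{tibble: `subject_id`, `group` (factor
#'       control/case), `age`, `sex`, `serum_creatinine`, `tnm_stage`,
#'       `t_stage`, `histology` (cases only for the last three).}
#'     \item{ct}{tibble: `sample_id`, `assay_id`, `assay_role`
#'       (`candidate_marker` / `internal_control_candidate`), `replicate`,
#'       `ct` (cycles; `NA` = undetermined).}
#'   }
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_control = 20, n_case = 10))
#' head(cohort$subjects)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be created by simulation_config().")
  }
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_control + cfg$n_case
  ids <- sprintf("S%04d", seq_len(n))
  group <- factor(rep(c("control", "case"), c(cfg$n_control, cfg$n_case)),
                  levels = c("control", "case"))

  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    while (any(out <- x < lo | x > hi)) x[out] <- rnorm(sum(out), mean, sd)
    x
  }
  age <- rtnorm(n, cfg$age_mean + ifelse(group == "case", cfg$age_shift_case, 0),
                cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
  sex <- factor(ifelse(runif(n) < cfg$female_prop, "female", "male"),
                levels = c("female", "male"))
  creat <- rlnorm(n, cfg$creatinine_meanlog, cfg$creatinine_sdlog)

  # latent stage variable for cases; coupled to the designated marker's Ct
  # noise via a Gaussian copula (Pearson latent rho = 2*sin(pi*rho_s/6))
  stage_levels <- c("I", "II", "III", "IV")
  z_stage <- rnorm(cfg$n_case)
  has_corr <- !is.null(cfg$stage_corr_marker) && !is.null(cfg$stage_corr_rho)
  if (has_corr) {
    # expression decreases as Ct increases, so Spearman(expr, stage) = rho
    # requires Spearman(Ct, stage) = -rho on the latent scale
    rho_lat <- 2 * sin(pi * (-cfg$stage_corr_rho) / 6)
    z_ct_corr <- rho_lat * z_stage + sqrt(1 - rho_lat^2) * rnorm(cfg$n_case)
  }
  stage_idx <- findInterval(pnorm(z_stage), cumsum(cfg$stage_probs)) + 1L
  stage_idx <- pmin(stage_idx, 4L)
  tnm_stage <- factor(stage_levels[stage_idx], levels = stage_levels,
                      ordered = TRUE)
  t_stage <- factor(sample(c("T1", "T2", "T3", "T4"), cfg$n_case,
                           replace = TRUE, prob = c(21, 1, 10, 11) / 43),
                    levels = c("T1", "T2", "T3", "T4"), ordered = TRUE)

  subjects <- tibble(
    subject_id = ids, group = group, age = age, sex = sex,
    serum_creatinine = creat,
    tnm_stage = c(rep(NA_character_, cfg$n_control),
                  as.character(tnm_stage)),
    t_stage = c(rep(NA_character_, cfg$n_control), as.character(t_stage)),
    histology = c(rep(NA_character_, cfg$n_control),
                  rep("squamous cell carcinoma", cfg$n_case))
  )

  markers <- cfg$marker_specs
  ic_names <- c("miR-4669", "miR-6756-5p",
                sprintf("IC-%d", seq_len(max(0, cfg$n_internal_controls - 2L)) + 2L))
  ic_names <- ic_names[seq_len(cfg$n_internal_controls)]
  assays <- c(markers$name, ic_names)
  roles <- rep(c("candidate_marker", "internal_control_candidate"),
               c(nrow(markers), length(ic_names)))
  baselines <- cfg$baseline_ct
  if (is.null(baselines)) {
    baselines <- stats::setNames(
      seq(24, 34, length.out = length(assays)), assays
    )
  }

  is_case <- group == "case"
  ct_cells <- purrr::map(seq_along(assays), function(j) {
    a <- assays[j]
    if (roles[j] == "candidate_marker") {
      spec <- markers[markers$name == a, ]
      z <- rnorm(n)
      if (has_corr && identical(a, cfg$stage_corr_marker)) {
        z[is_case] <- z_ct_corr
      }
      mu <- baselines[[a]] - ifelse(is_case, spec$delta_ct_shift, 0)
      ct <- mu + spec$noise_sd * z
    } else {
      ct <- baselines[[a]] + cfg$internal_control_sd * rnorm(n)
    }
    tibble(sample_id = ids, assay_id = a, assay_role = roles[j],
           replicate = 1L, ct = pmin(pmax(ct, 1), 45))
  })
  ct1 <- bind_rows(ct_cells)

  if (cfg$replicate_count > 1L) {
    reps <- purrr::map(2:cfg$replicate_count, function(r) {
      mutate(ct1, replicate = as.integer(r),
             ct = pmin(pmax(.data$ct + rnorm(dplyr::n(), 0, cfg$replicate_sd),
                            1), 45))
    })
    ct_tbl <- bind_rows(ct1, reps) %>%
      arrange(.data$sample_id, .data$assay_id, .data$replicate)
  } else {
    ct_tbl <- arrange(ct1, .data$sample_id, .data$assay_id, .data$replicate)
  }

  structure(list(subjects = subjects, ct = ct_tbl, config = cfg),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d controls, %d cases; %d assays x %d replicates\n",
    sum(x$subjects$group == "control"), sum(x$subjects$group == "case"),
    length(unique(x$ct$assay_id)), max(x$ct$replicate)
  ))
  invisible(x)
}

#' Remove poor-quality samples from a Ct matrix
#'
#' Flags each sample as poor quality independently with probability `rate`
#' (seeded) and removes all of its rows, emulating the exclusion of urine
#' samples whose miRNA quality fails QC.
#'
#' @param ct A long-format Ct tibble (as produced by [simulate_cohort()]).
#' @param rate Failure probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list with `ct` (the retained rows) and `excluded` (character
#'   vector of excluded sample ids, disjoint from the retained ids).
#' @export
apply_quality_failures <- function(ct, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) {
    abort("`rate` must lie in [0, 1).", class = "uromir_config_error")
  }
  samples <- unique(ct$sample_id)
  excluded <- withr::with_seed(seed, samples[runif(length(samples)) < rate])
  if (length(excluded) == length(samples)) {
    abort("All samples were flagged poor quality; empty cohort.",
          class = "uromir_empty_cohort_error")
  }
  list(ct = filter(ct, !.data$sample_id %in% excluded), excluded = excluded)
}
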