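# Discovery-stage differential screening: fold change + Mann-Whitney test
# per marker, followed by a detection-rate stability filter.

#' Differential screening of candidate markers
#'
#' For each marker, computes the case/control fold change of relative
#' expression, a two-sided Mann-Whitney p-value, and per-group detection
#' rates (fraction of samples with a determined measurement). A marker is
#' `selected` when its fold change exceeds `fc_threshold` in either
#' direction (`> fc_threshold` or `< 1/fc_threshold`), its p-value is below
#' `alpha`, and both detection rates reach `min_detect_rate`. No
#' multiple-testing correction is applied at this discovery stage; the raw
#' per-marker threshold mirrors conventional microarray screening.
#'
#' @param expr Expression tibble from [delta_ct()] (`sample_id`,
#'   `marker_id`, `rel_expr`).
#' @param subjects Subject tibble supplying `subject_id` and `group`.
#' @param fc_threshold Fold-change threshold (default 2.0).
#' @param alpha Significance threshold (default 0.05).
#' @param center `"mean"` (conventional fold change, default) or
#'   `"median"`.
#' @param min_detect_rate Detection-rate floor entering the `selected`
#'   flag (default 0; use [stability_filter()] to filter afterwards).
#' @return A tibble sorted by p-value: `marker_id`, `n_case`, `n_control`,
#'   `fold_change`, `direction`, `p_value`, `detect_rate_case`,
#'   `detect_rate_control`, `selected`. Markers with fewer than 2 usable
#'   values in either group are skipped with a warning.
#' @export
differential_screen <- function(expr, subjects, fc_threshold = 2.0,
                                alpha = 0.05,
                                center = c("mean", "median"),
                                min_detect_rate = 0) {
  center <- arg_match(center)
  cfun <- if (center == "mean") mean else median
  dat <- expr %>%
    left_join(select(subjects, sample_id = "subject_id", "group"),
              by = "sample_id")
  if (anyNA(dat$group)) {
    abort("Some expression samples have no matching subject record.")
  }
  skipped <- character(0)
  out <- dat %>%
    group_by(.data$marker_id) %>%
    dplyr::group_map(function(d, key) {
      is_case <- as_case_logical(d$group)
      cs <- d$rel_expr[is_case]
      ct <- d$rel_expr[!is_case]
      det_case <- mean(!is.na(cs))
      det_ctrl <- mean(!is.na(ct))
      cs <- cs[!is.na(cs)]
      ct <- ct[!is.na(ct)]
      if (length(cs) < 2L || length(ct) < 2L) {
        skipped <<- c(skipped, key$marker_id)
        return(NULL)
      }
      fc <- cfun(cs) / cfun(ct)
      p <- mann_whitney(cs, ct)$p_value
      tibble(
        marker_id = key$marker_id,
        n_case = length(cs), n_control = length(ct),
        fold_change = fc,
        direction = if (fc > 1) "up" else "down",
        p_value = p,
        detect_rate_case = det_case,
        detect_rate_control = det_ctrl,
        selected = (fc > fc_threshold | fc < 1 / fc_threshold) &
          p < alpha &
          det_case >= min_detect_rate & det_ctrl >= min_detect_rate
      )
    }) %>%
    bind_rows(tibble(
      marker_id = character(), n_case = integer(), n_control = integer(),
      fold_change = numeric(), direction = character(),
      p_value = numeric(), detect_rate_case = numeric(),
      detect_rate_control = numeric(), selected = logical()
    ), .) %>%
    arrange(.data$p_value, .data$marker_id) %>%
    select("marker_id", "n_case", "n_control", "fold_change", "direction",
           "p_value", "detect_rate_case", "detect_rate_control", "selected")
  if (length(skipped)) {
    warn(paste0("Skipped marker(s) with < 2 usable values in a group: ",
                paste(skipped, collapse = ", ")))
  }
  out
}

#' Filter screen records by detection-rate stability
#'
#' Retains markers detected (finite measurement) in at least
#' `min_detect_rate` of samples in both groups, preserving the input
#' ordering. This operationalizes the requirement that qualified
#' candidates be stably expressed across the cohort.
#'
#' @param records Output of [differential_screen()].
#' @param min_detect_rate Detection-rate floor in `[0, 1]` (default 0.8).
#' @return The filtered tibble.
#' @export
stability_filter <- function(records, min_detect_rate = 0.8) {
  filter(records,
         .data$detect_rate_case >= min_detect_rate &
           .data$detect_rate_control >= min_detect_rate)
}
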