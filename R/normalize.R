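# qPCR normalization: replicate aggregation, data-driven selection of
# internal-control (reference) assays by a global-mean stability criterion,
# and 2^-dCt relative quantification.

#' Aggregate technical replicates of a Ct matrix
#'
#' Collapses each (sample, assay) cell to the arithmetic mean of its finite
#' replicate Ct values. Cells whose replicate range exceeds
#' `discordance_limit` are flagged (not removed); cells with all replicates
#' undetermined stay `NA`.
#'
#' @param ct Long-format Ct tibble: `sample_id`, `assay_id`, `assay_role`,
#'   `replicate`, `ct` (`NA` = undetermined).
#' @param discordance_limit Maximum tolerated replicate range in cycles
#'   (default 1.0).
#' @return A tibble with one row per (sample, assay): `sample_id`,
#'   `assay_id`, `assay_role`, `ct`, `n_replicates`, `discordant`.
#' @export
aggregate_replicates <- function(ct, discordance_limit = 1.0) {
  ct %>%
    group_by(.data$sample_id, .data$assay_id, .data$assay_role) %>%
    summarise(
      n_replicates = sum(!is.na(.data$ct)),
      discordant = .data$n_replicates > 1L &&
        diff(range(.data$ct, na.rm = TRUE)) > discordance_limit,
      ct = if (all(is.na(.data$ct))) NA_real_ else
        mean(.data$ct, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    select("sample_id", "assay_id", "assay_role", "ct",
           "n_replicates", "discordant") %>%
    arrange(.data$sample_id, .data$assay_id)
}

#' Select internal-control assays by global-mean stability
#'
#' Implements global-mean normalization for reference selection: for each
#' sample the global mean Ct over all assays is computed; each assay is
#' scored by the SD across samples of its deviation from that per-sample
#' global mean. The `n_controls` assays with the smallest score (most
#' faithful trackers of the global mean) are returned; ties are broken by
#' assay id. Only assays with a finite Ct in every sample are eligible.
#'
#' @param ct_agg Replicate-aggregated Ct tibble (see
#'   [aggregate_replicates()]); a raw replicate-level table is aggregated
#'   first.
#' @param n_controls Number of reference assays to select (default 2).
#' @return Character vector of selected assay ids, with the full score
#'   table attached as attribute `"scores"` (tibble: `assay_id`, `score`,
#'   `selected`).
#' @export
select_internal_controls <- function(ct_agg, n_controls = 2L) {
  if ("replicate" %in% names(ct_agg)) {
    ct_agg <- aggregate_replicates(ct_agg)
  }
  # per-sample global mean over all assays with a finite Ct
  with_gm <- ct_agg %>%
    group_by(.data$sample_id) %>%
    mutate(global_mean = mean(.data$ct, na.rm = TRUE)) %>%
    ungroup()
  complete <- with_gm %>%
    group_by(.data$assay_id) %>%
    summarise(complete = all(is.finite(.data$ct)),
              score = sd(.data$ct - .data$global_mean),
              .groups = "drop")
  eligible <- filter(complete, .data$complete)
  if (nrow(eligible) < n_controls) {
    abort(
      paste0(
        "Too few assays with complete Ct across samples (need ",
        n_controls, ", have ", nrow(eligible), "). Incomplete assays: ",
        paste(complete$assay_id[!complete$complete], collapse = ", ")
      ),
      class = "uromir_selection_error"
    )
  }
  scores <- eligible %>%
    arrange(.data$score, .data$assay_id) %>%
    mutate(selected = dplyr::row_number() <= n_controls) %>%
    select("assay_id", "score", "selected")
  out <- scores$assay_id[scores$selected]
  attr(out, "scores") <- scores
  out
}

#' Relative expression by the 2^-dCt method
#'
#' For every sample the reference Ct is the arithmetic mean of the
#' internal-control assays' Ct (equivalently the geometric mean of their
#' expression); each marker's `delta_ct` is its Ct minus the reference Ct
#' and `rel_expr = 2^-delta_ct`. Markers with undetermined Ct yield missing
#' entries, never zeros. Samples missing a finite Ct for any reference
#' assay are excluded with a warning and listed in the attribute
#' `"excluded_samples"`.
#'
#' @param ct_agg Replicate-aggregated Ct tibble; a replicate-level table is
#'   aggregated first with defaults.
#' @param reference_assays Character vector of internal-control assay ids.
#' @return A tibble of class `expression_tbl`: `sample_id`, `marker_id`,
#'   `delta_ct`, `rel_expr`, with attributes `reference_assays` and
#'   `excluded_samples`.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = "S1", assay_id = c("m1", "ref"),
#'   assay_role = c("candidate_marker", "internal_control_candidate"),
#'   replicate = 1L, ct = c(25, 20)
#' )
#' delta_ct(ct, "ref") # rel_expr = 2^-5
#' @export
delta_ct <- function(ct_agg, reference_assays) {
  if ("replicate" %in% names(ct_agg)) {
    ct_agg <- aggregate_replicates(ct_agg)
  }
  if (!all(reference_assays %in% ct_agg$assay_id)) {
    abort("All `reference_assays` must appear in the Ct table.")
  }
  ref <- ct_agg %>%
    filter(.data$assay_id %in% reference_assays) %>%
    group_by(.data$sample_id) %>%
    summarise(ref_ct = mean(.data$ct),
              ref_ok = all(is.finite(.data$ct)), .groups = "drop")
  excluded <- ref$sample_id[!ref$ref_ok]
  if (length(excluded)) {
    warn(paste0(
      "Excluding ", length(excluded),
      " sample(s) missing a finite reference Ct: ",
      paste(excluded, collapse = ", ")
    ))
  }
  out <- ct_agg %>%
    filter(!.data$assay_id %in% reference_assays) %>%
    left_join(filter(ref, .data$ref_ok), by = "sample_id") %>%
    filter(!is.na(.data$ref_ct)) %>%
    mutate(delta_ct = .data$ct - .data$ref_ct,
           rel_expr = 2^(-.data$delta_ct)) %>%
    select(marker_id = "assay_id", "sample_id", "delta_ct", "rel_expr") %>%
    select("sample_id", "marker_id", "delta_ct", "rel_expr") %>%
    arrange(.data$sample_id, .data$marker_id)
  attr(out, "reference_assays") <- reference_assays
  attr(out, "excluded_samples") <- excluded
  class(out) <- c("expression_tbl", class(out))
  out
}
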