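# Round-trippable plain-text I/O: subjects CSV, long-format Ct CSV, and a
# key:value (YAML) representation of the simulation configuration.

#' @rdname cohort_io
#' @export
write_subjects_csv <- function(subjects, path) {
  readr::write_csv(subjects, path, na = "NA")
  invisible(path)
}

#' Read and write cohort tables
#'
#' Subjects are stored as plain CSV (`subject_id`, `group`, `age`, `sex`,
#' `serum_creatinine`, `tnm_stage`, `t_stage`, ...); Ct matrices as
#' long-format CSV (`sample_id`, `assay_id`, `assay_role`, `replicate`,
#' `ct`) with `NA` marking undetermined reactions. Reading restores the
#' column types used throughout the package, so write/read round-trips are
#' lossless.
#'
#' @param subjects,ct Tibbles to write.
#' @param path File path.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @name cohort_io
#' @export
read_subjects_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) %>%
    mutate(
      group = factor(.data$group, levels = c("control", "case")),
      sex = factor(.data$sex, levels = c("female", "male"))
    )
}

#' @rdname cohort_io
#' @export
write_ct_csv <- function(ct, path) {
  readr::write_csv(ct, path, na = "NA")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_ct_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      assay_id = readr::col_character(),
      assay_role = readr::col_character(),
      replicate = readr::col_integer(),
      ct = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Write or read a simulation configuration as key:value text
#'
#' The configuration is serialized as YAML (marker specifications as a
#' list of name/shift/SD entries) and restored through
#' [simulation_config()], so a read-back configuration is re-validated and
#' generates identical cohorts.
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @return The path (writer, invisibly) or the restored config (reader).
#' @export
write_simulation_config <- function(config, path) {
  x <- unclass(config)
  x$marker_specs <- purrr::pmap(config$marker_specs, list)
  writeLines(yaml::as.yaml(x, precision = 17L), path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$marker_specs <- bind_rows(lapply(x$marker_specs, as_tibble))
  x$stage_probs <- as.numeric(x$stage_probs)
  x$age_range <- as.numeric(x$age_range)
  if (!is.null(x$baseline_ct)) x$baseline_ct <- unlist(x$baseline_ct)
  do.call(simulation_config, x)
}
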