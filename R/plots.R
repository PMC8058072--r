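# ggplot2 visualizations for the main result types.

#' Plot a ROC curve
#'
#' @param object A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- attr(object, "curve")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f [%.3f-%.3f]", object$auc, object$ci_low,
                      object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validated AUCs
#'
#' @param object A [kfold_cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("train_auc", "test_auc"), names_to = "set",
                        values_to = "auc") %>%
    mutate(set = ifelse(.data$set == "train_auc", "train", "test"))
  means <- tibble(
    set = c("train", "test"),
    auc = c(object$mean_train_auc, object$mean_test_auc)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$auc)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.05),
                        alpha = 0.7) +
    ggplot2::geom_point(data = means, colour = "red", shape = 18, size = 4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "AUC",
                  title = sprintf("%d-fold cross-validated AUC", object$k)) +
    ggplot2::theme_minimal()
}

#' Covariate-balance (Love) plot for a matching result
#'
#' Standardized differences before and after matching, with the
#' conventional 0.1 reference line.
#'
#' @param object A [match_nearest_neighbor()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.match_result <- function(object, ...) {
  d <- object$balance %>%
    select("covariate", "d_pre", "d_post") %>%
    tidyr::pivot_longer(c("d_pre", "d_post"), names_to = "when",
                        values_to = "d") %>%
    mutate(when = ifelse(.data$when == "d_pre", "before", "after"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$d, y = .data$covariate,
                                  colour = .data$when)) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Absolute standardized difference", y = NULL,
                  colour = "Matching") +
    ggplot2::theme_minimal()
}

#' Marker expression by group
#'
#' Box plots (log scale) of relative expression per marker and group.
#'
#' @param expr Expression tibble from [delta_ct()].
#' @param subjects Subject tibble (`subject_id`, `group`).
#' @param markers Optional character vector restricting the markers shown.
#' @return A ggplot.
#' @export
plot_marker_expression <- function(expr, subjects, markers = NULL) {
  d <- expr %>%
    left_join(select(subjects, sample_id = "subject_id", "group"),
              by = "sample_id") %>%
    filter(!is.na(.data$rel_expr))
  if (!is.null(markers)) d <- filter(d, .data$marker_id %in% markers)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$rel_expr,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~marker_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta * Ct})) +
    ggplot2::theme_minimal()
}
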