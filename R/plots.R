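# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a prevalence table
#'
#' Per-measure prevalence bars, split by anticoagulant molecule.
#'
#' @param object a `pimddi_prevalence` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pimddi_prevalence <- function(object, ...) {
  df <- object |>
    filter(.data$measure %in% c("anticoagulant", "pim", "ddi", "pim_ddi"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$pct,
                                   fill = .data$drug)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "% of exposed patients", fill = "molecule",
      title = sprintf("Prevalence (%s setting)", unique(df$setting))
    ) +
    ggplot2::theme_minimal()
}

#' Plot pathway flow counts
#'
#' @param object a `pimddi_flows` tibble from [aggregate_flows()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pimddi_flows <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$category, .data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n,
                                                    .data$pct)),
                       hjust = -0.05, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "patients",
                  title = "Anticoagulant treatment pathway") +
    ggplot2::theme_minimal()
}

#' ROC curve of a fitted model on a data set
#'
#' @param model a `pimddi_model`
#' @param data tibble with features and the outcome column
#' @return a ggplot of the ROC curve with its trapezoidal AUC
#' @export
plot_roc <- function(model, data) {
  scores <- predict(model, data)
  labels <- as.logical(data[[model$outcome]])
  pts <- roc_points(scores, labels) |> arrange(.data$fpr, .data$sensitivity)
  auc <- auc_trapezoid(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_path(color = "firebrick") +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("%s (AUC %.3f)", model$family, auc)) +
    ggplot2::theme_minimal()
}

#' Variable-importance bar chart
#'
#' @param model a tree-ensemble `pimddi_model`
#' @param top_n number of features shown (default 15)
#' @return a ggplot
#' @export
plot_importance <- function(model, top_n = 15) {
  imp <- variable_importance(model) |> head(top_n)
  ggplot2::ggplot(imp,
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$importance),
                               y = .data$importance)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized gain",
                  title = "Variable importance") +
    ggplot2::theme_minimal()
}
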