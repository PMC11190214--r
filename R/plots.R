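#' Plot a Shapley explanation
#'
#' Horizontal bar chart of the per-player attributions for one label,
#' alive-positive, most influential players first.
#'
#' @param object A `shap_explanation`.
#' @param label Label to plot (default `"alive"`).
#' @param top_n Players shown (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shap_explanation <- function(object, label = "alive",
                                      top_n = 20L, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$label == !!label) |>
    dplyr::mutate(name = ifelse(is.na(.data$token), .data$feature,
                                paste0(.data$feature, ": ",
                                       .data$token))) |>
    dplyr::arrange(dplyr::desc(abs(.data$value))) |>
    utils::head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$value,
    y = stats::reorder(.data$name, abs(.data$value)),
    fill = .data$value > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = paste("Shapley value towards", label), y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked importance-proportion bars across models
#'
#' The dataset-level comparison of where each architecture puts its
#' importance: one horizontal stacked bar per model, segment widths equal
#' to each feature's share of total mean absolute importance. Features
#' beyond `top_n` (ranked across all models) are pooled into `"other"`.
#'
#' @param summaries Named list of [summarise_importance()] tibbles, one
#'   per model.
#' @param top_n Features kept before pooling into `"other"` (default 6).
#' @return A ggplot object.
#' @export
plot_importance_proportions <- function(summaries, top_n = 6L) {
  df <- dplyr::bind_rows(summaries, .id = "model")
  keep <- df |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(p = max(.data$proportion), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$p)) |>
    utils::head(top_n)
  df <- df |>
    dplyr::mutate(feature = ifelse(.data$feature %in% keep$feature,
                                   .data$feature, "other")) |>
    dplyr::group_by(.data$model, .data$feature) |>
    dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proportion, y = .data$model,
                                   fill = .data$feature)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "share of mean |phi|", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of per-instance importance differences by group
#'
#' @param object An [importance_difference()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_difference <- function(object, ...) {
  ggplot2::ggplot(object$differences,
                  ggplot2::aes(x = .data$group, y = .data$diff)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      y = paste0("phi[", object$feature_x, "] - phi[",
                 object$feature_y, "]"),
      x = NULL) +
    ggplot2::theme_minimal()
}
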