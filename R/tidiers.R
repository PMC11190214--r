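#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Shapley explanation into a long tibble
#'
#' @param x A `shap_explanation`.
#' @param ... Unused.
#' @return Tibble with one row per player x label: player columns (the
#'   rendered tabular value as `tabular_value`) plus `label`, `value`
#'   (the attribution), and `se` when the sampling estimator produced
#'   one.
#' @export
tidy.shap_explanation <- function(x, ...) {
  pl <- dplyr::rename(x$players, tabular_value = "value")
  long <- tidyr::expand_grid(player_id = pl$player_id,
                             label = x$labels) |>
    dplyr::left_join(pl, by = "player_id")
  long$value <- as.numeric(t(x$values))
  if (!is.null(x$se)) long$se <- as.numeric(t(x$se))
  long[, c(names(pl), "label", "value",
           if (!is.null(x$se)) "se")]
}

#' One-row summary of a Shapley explanation
#'
#' @param x A `shap_explanation`.
#' @param ... Unused.
#' @return One-row tibble: player counts, estimator, base values, model
#'   outputs and the per-label efficiency gap.
#' @export
glance.shap_explanation <- function(x, ...) {
  gap <- efficiency_gap(x)
  tibble::tibble(
    n_players = nrow(x$players),
    n_text = sum(x$players$modality == "text"),
    n_tabular = sum(x$players$modality == "tabular"),
    estimator = x$estimator,
    n_permutations = x$n_permutations,
    base_alive = x$base_values[[1L]],
    output_alive = x$model_output[[1L]],
    max_abs_efficiency_gap = max(abs(gap))
  )
}

#' @rdname tidy.shap_explanation
#' @export
tidy.rank_comparison <- function(x, ...) x$per_instance

#' @rdname glance.shap_explanation
#' @export
glance.rank_comparison <- function(x, ...) {
  tibble::tibble(mean_tau = x$mean, sd_tau = x$sd, n = x$n)
}

#' @rdname tidy.shap_explanation
#' @export
tidy.importance_difference <- function(x, ...) x$differences

#' @rdname glance.shap_explanation
#' @export
glance.importance_difference <- function(x, ...) {
  tibble::tibble(h = x$h, p_value = x$p_value, epsilon_sq = x$epsilon_sq)
}

#' @rdname glance.shap_explanation
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(f1 = x$f1, accuracy = x$accuracy, n = x$n,
                 positive = x$positive)
}
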