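#' Aggregate player attributions into per-feature importance
#'
#' Collapses word-piece-level Shapley values to one non-negative score per
#' feature: within each feature the player values are summed per label,
#' the absolute value taken, and the two labels added,
#' \deqn{\phi_f = |\sum_{t \in f} v_{t,alive}| + |\sum_{t \in f} v_{t,dead}|.}
#' For probability-pair models (where the two labels' values are exact
#' negatives) this equals twice the absolute summed alive-label value.
#'
#' @param explanation A `shap_explanation`.
#' @param features Optional character vector fixing the feature set and
#'   order; features without players get `phi = 0`.
#' @return Tibble with `feature` and `phi`.
#' @export
phi_aggregate <- function(explanation, features = NULL) {
  stopifnot(inherits(explanation, "shap_explanation"))
  pl <- explanation$players
  if (any(is.na(pl$feature))) {
    stop("consistency error: player mapped to no feature", call. = FALSE)
  }
  v <- explanation$values
  df <- tibble::tibble(feature = pl$feature,
                       a = v[, 1L], d = v[, 2L]) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(phi = abs(sum(.data$a)) + abs(sum(.data$d)),
                     .groups = "drop")
  if (!is.null(features)) {
    df <- tibble::tibble(feature = features) |>
      dplyr::left_join(df, by = "feature") |>
      dplyr::mutate(phi = dplyr::coalesce(.data$phi, 0))
  }
  df
}

#' Dataset-level importance proportions
#'
#' Mean absolute feature importance per feature across instances, as a
#' proportion of the sum over features — the summary used to compare how
#' much each architecture leans on each feature. Proportions sum to 1.
#'
#' @param phi_tbl Long tibble with `instance`, `feature`, `phi` columns
#'   (e.g. bound rows of [phi_aggregate()] outputs), or a list of
#'   per-instance `phi` tibbles.
#' @return Tibble with `feature`, `mean_abs_phi`, `proportion`, sorted by
#'   decreasing proportion.
#' @export
summarise_importance <- function(phi_tbl) {
  if (is.list(phi_tbl) && !is.data.frame(phi_tbl)) {
    phi_tbl <- dplyr::bind_rows(phi_tbl, .id = "instance")
  }
  stopifnot(all(c("feature", "phi") %in% names(phi_tbl)))
  if (nrow(phi_tbl) == 0L) stop("empty importance input", call. = FALSE)
  out <- phi_tbl |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_abs_phi = mean(abs(.data$phi)),
                     .groups = "drop") |>
    dplyr::mutate(proportion = .data$mean_abs_phi /
                    sum(.data$mean_abs_phi)) |>
    dplyr::arrange(dplyr::desc(.data$proportion))
  out
}

#' Kendall's rank correlation between two importance vectors
#'
#' The pairwise form \eqn{\tau = (C - D) / \binom{n}{2}}: over all feature
#' pairs, concordant minus discordant, divided by the total number of
#' pairs. Ties count as neither concordant nor discordant while remaining
#' in the denominator (the tau-a convention implied by the printed
#' formula); with continuous importance scores ties have measure zero.
#' Identical rankings score 1, exactly reversed rankings -1.
#'
#' @param rank_a,rank_b Numeric vectors of per-feature importance over the
#'   same features (matched by name when both are named), length >= 2.
#' @return tau in \[-1, 1\].
#' @export
#' @examples
#' kendall_tau(c(3, 2, 1), c(3, 1, 2))  # 1/3
kendall_tau <- function(rank_a, rank_b) {
  if (!is.null(names(rank_a)) && !is.null(names(rank_b))) {
    if (!setequal(names(rank_a), names(rank_b))) {
      stop("importance vectors cover different features", call. = FALSE)
    }
    rank_b <- rank_b[names(rank_a)]
  }
  n <- length(rank_a)
  if (n < 2L || length(rank_b) != n) {
    stop("need >= 2 features in both vectors", call. = FALSE)
  }
  pairs <- utils::combn(n, 2L)
  da <- rank_a[pairs[1L, ]] - rank_a[pairs[2L, ]]
  db <- rank_b[pairs[1L, ]] - rank_b[pairs[2L, ]]
  s <- sign(da) * sign(db)
  (sum(s > 0) - sum(s < 0)) / ncol(pairs)
}

#' Compare feature rankings across instances
#'
#' For each aligned instance, computes Kendall's tau between the two
#' feature-importance rankings, then summarises the per-instance values
#' with their mean and standard deviation — the rank-stability statistic
#' used to compare explanation sets produced by different architectures
#' or text models.
#'
#' @param phi_a,phi_b Long tibbles with `instance`, `feature`, `phi`,
#'   covering the same instances and features one-to-one.
#' @return A `rank_comparison`: list with `per_instance` (tibble
#'   `instance`, `tau`), `mean`, `sd`, `n`.
#' @seealso [pool_comparisons()] for the pooled "Total" row across
#'   several comparisons.
#' @export
compare_rankings <- function(phi_a, phi_b) {
  stopifnot(all(c("instance", "feature", "phi") %in% names(phi_a)),
            all(c("instance", "feature", "phi") %in% names(phi_b)))
  if (!setequal(unique(phi_a$instance), unique(phi_b$instance))) {
    stop("misaligned instances between the two explanation sets",
         call. = FALSE)
  }
  wide_a <- split(phi_a, phi_a$instance)
  wide_b <- split(phi_b, phi_b$instance)
  ids <- names(wide_a)
  tau <- vapply(ids, function(id) {
    a <- stats::setNames(wide_a[[id]]$phi, wide_a[[id]]$feature)
    b <- stats::setNames(wide_b[[id]]$phi, wide_b[[id]]$feature)
    kendall_tau(a, b)
  }, numeric(1))
  per_instance <- tibble::tibble(instance = ids, tau = unname(tau))
  structure(
    list(per_instance = per_instance, mean = mean(per_instance$tau),
         sd = stats::sd(per_instance$tau), n = nrow(per_instance)),
    class = "rank_comparison"
  )
}

#' Pool several rank comparisons into a "Total" summary
#'
#' Concatenates the raw per-instance tau values of multiple comparisons
#' and recomputes mean and SD over the pooled values (not a mean of
#' means).
#'
#' @param comparisons List of `rank_comparison` objects.
#' @return A pooled `rank_comparison`.
#' @export
pool_comparisons <- function(comparisons) {
  stopifnot(length(comparisons) > 0L)
  per <- dplyr::bind_rows(lapply(comparisons, function(x) x$per_instance))
  structure(
    list(per_instance = per, mean = mean(per$tau), sd = stats::sd(per$tau),
         n = nrow(per)),
    class = "rank_comparison"
  )
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("<rank_comparison> mean tau %.3f (SD %.3f), n = %d\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Per-instance importance differences between two features, by group
#'
#' For each instance computes `phi[feature_x] - phi[feature_y]` and tests
#' whether the difference distributions differ across groups (combination
#' methods) with a Kruskal-Wallis H test; reports epsilon-squared,
#' `H / ((n^2 - 1) / (n + 1))`, as the share of rank variance explained by
#' the grouping.
#'
#' @param phi_tbl Long tibble `instance`, `feature`, `phi`, `group`.
#' @param feature_x,feature_y Feature names; both must appear in every
#'   instance.
#' @return An `importance_difference`: list with `differences` (tibble
#'   `instance`, `group`, `diff`), `h`, `p_value`, `epsilon_sq`.
#' @export
importance_difference <- function(phi_tbl, feature_x, feature_y) {
  stopifnot(all(c("instance", "feature", "phi", "group") %in%
                  names(phi_tbl)))
  wide <- phi_tbl |>
    dplyr::filter(.data$feature %in% c(feature_x, feature_y)) |>
    tidyr::pivot_wider(id_cols = c("instance", "group"),
                       names_from = "feature", values_from = "phi")
  if (!all(c(feature_x, feature_y) %in% names(wide)) ||
      anyNA(wide[[feature_x]]) || anyNA(wide[[feature_y]])) {
    stop("both features must be present in every instance", call. = FALSE)
  }
  diffs <- wide |>
    dplyr::transmute(.data$instance, .data$group,
                     diff = .data[[feature_x]] - .data[[feature_y]])
  sizes <- table(diffs$group)
  if (any(sizes < 2L)) {
    stop("each group needs >= 2 instances", call. = FALSE)
  }
  n <- nrow(diffs)
  if (length(unique(diffs$diff)) == 1L) {
    # all observations tied: no rank variation, H = 0 by definition
    # (kruskal.test's tie correction degenerates to 0/0 here)
    h <- 0
    kw <- list(p.value = 1)
  } else {
    kw <- stats::kruskal.test(diff ~ factor(group), data = diffs)
    h <- unname(kw$statistic)
  }
  structure(
    list(differences = diffs, h = h, p_value = kw$p.value,
         epsilon_sq = h / ((n^2 - 1) / (n + 1)),
         feature_x = feature_x, feature_y = feature_y),
    class = "importance_difference"
  )
}

#' @export
print.importance_difference <- function(x, ...) {
  cat(sprintf(
    "<importance_difference> %s - %s: H = %.2f, p = %.3g, eps^2 = %.2f\n",
    x$feature_x, x$feature_y, x$h, x$p_value, x$epsilon_sq))
  invisible(x)
}

#' Most and least alive-contributing phrases and tabular values
#'
#' Turns player-level attributions into ranked phrases: adjacent
#' word-pieces of one word (continuation pieces) are always merged, and
#' adjacent words of the same feature are further merged into phrases
#' when their values share a sign and their magnitude ratio
#' `min(|a|,|b|) / max(|a|,|b|)` exceeds `grouping_threshold` (merged
#' value = sum of member values). Tabular players are rendered as
#' `"feature = value"`. Strings occurring more than once are averaged.
#' Signed values follow the alive-positive convention: positive
#' contributes towards `alive`, negative towards `dead`.
#'
#' @param explanations List of `shap_explanation`s.
#' @param grouping_threshold Word-merge cohesion threshold in \[0, 1\];
#'   default 0.4.
#' @param k List length (default 5).
#' @param exclude_features Features to drop before ranking (e.g. the
#'   dominant tabular feature).
#' @return Tibble with `direction` (`"top"`/`"bottom"`), `phrase`,
#'   `mean_value`, `n_occurrences`; top = most alive-contributing.
#' @export
top_phrases <- function(explanations, grouping_threshold = 0.4, k = 5L,
                        exclude_features = NULL) {
  if (inherits(explanations, "shap_explanation")) {
    explanations <- list(explanations)
  }
  items <- dplyr::bind_rows(lapply(explanations, phrase_items,
                                   grouping_threshold = grouping_threshold))
  if (!is.null(exclude_features)) {
    items <- dplyr::filter(items, !.data$feature %in% exclude_features)
  }
  scores <- items |>
    dplyr::group_by(.data$phrase) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     n_occurrences = dplyr::n(), .groups = "drop")
  top <- scores |>
    dplyr::arrange(dplyr::desc(.data$mean_value)) |>
    utils::head(k) |>
    dplyr::mutate(direction = "top")
  bottom <- scores |>
    dplyr::arrange(.data$mean_value) |>
    utils::head(k) |>
    dplyr::mutate(direction = "bottom") |>
    dplyr::arrange(dplyr::desc(.data$mean_value))
  dplyr::bind_rows(top, bottom)[, c("direction", "phrase", "mean_value",
                                    "n_occurrences")]
}

# One explanation -> tibble(feature, phrase, value) of merged phrases and
# "feature = value" tabular entries, signed alive-positive.
phrase_items <- function(explanation, grouping_threshold) {
  pl <- explanation$players
  alive_col <- match("alive", explanation$labels)
  if (is.na(alive_col)) alive_col <- 1L
  signed <- explanation$values[, alive_col]

  out <- list()
  tab <- pl$modality == "tabular"
  if (any(tab)) {
    out[[1]] <- tibble::tibble(
      feature = pl$feature[tab],
      phrase = paste(pl$feature[tab], "=",
                     ifelse(is.na(pl$value[tab]), "", pl$value[tab])),
      value = signed[tab])
  }

  txt_idx <- which(pl$modality == "text")
  if (length(txt_idx) > 0L) {
    for (f in unique(pl$feature[txt_idx])) {
      idx <- txt_idx[pl$feature[txt_idx] == f]
      idx <- idx[order(pl$position[idx])]
      toks <- pl$token[idx]
      vals <- signed[idx]
      # pieces -> words: continuation pieces always merge left
      word_id <- cumsum(!startsWith(toks, "##"))
      words <- vapply(split(toks, word_id), function(p) {
        paste0(p[1], paste(sub("^##", "", p[-1]), collapse = ""))
      }, "")
      wvals <- vapply(split(vals, word_id), sum, numeric(1))
      # words -> phrases: greedy left-to-right cohesion merge
      phrase_id <- integer(length(words))
      cur <- 1L
      phrase_id[1L] <- 1L
      for (j in seq_along(words)[-1]) {
        a <- wvals[j - 1L]; b <- wvals[j]
        cohesive <- sign(a) == sign(b) && a != 0 && b != 0 &&
          min(abs(a), abs(b)) / max(abs(a), abs(b)) > grouping_threshold
        if (!cohesive) cur <- cur + 1L
        phrase_id[j] <- cur
      }
      phrases <- vapply(split(words, phrase_id), paste, "",
                        collapse = " ")
      pvals <- vapply(split(wvals, phrase_id), sum, numeric(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        feature = f, phrase = unname(phrases), value = unname(pvals))
    }
  }
  dplyr::bind_rows(out)
}
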