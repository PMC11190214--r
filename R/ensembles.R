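#' Route high-cardinality tabular features to the text side
#'
#' Categorical tabular features with strictly more unique values over
#' `records` than the schema's `cardinality_threshold` (default 30) are
#' moved to `text_features`: one-hot or ordinal encodings of such
#' features (breed, region) are poor, whereas a text model reads their
#' values directly. Numeric features are never routed — the encoding
#' problem the rule addresses does not arise for them. Idempotent:
#' re-applying changes nothing.
#'
#' @param records Record tibble (non-empty).
#' @param schema A [feature_schema()].
#' @return Updated `feature_schema` with `routed_features` attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_animals = 60, seed = 1))
#' route_high_cardinality(cohort$records, feature_schema())$text_features
route_high_cardinality <- function(records, schema = feature_schema()) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  tab <- schema$tabular_features
  counts <- vapply(names(tab), function(f) {
    dplyr::n_distinct(records[[f]], na.rm = TRUE)
  }, integer(1))
  routed <- names(tab)[tab == "categorical" &
                         counts > schema$cardinality_threshold]
  out <- schema
  out$tabular_features <- tab[setdiff(names(tab), routed)]
  out$text_features <- unique(c(routed, schema$text_features))
  attr(out, "routed_features") <- unique(c(attr(schema, "routed_features"),
                                           routed))
  out
}

#' Serialise a record into the All-Text template
#'
#' Renders the tabular fields as `"Name: value | Name: value | ..."` in
#' schema order and appends the text features with the same template, so a
#' text-only model can consume the full record. Returns the string along
#' with the character span of each feature's rendered value, which is what
#' lets attributions on the rendered string map back to features.
#'
#' @param record One-row record tibble.
#' @param schema A [feature_schema()] (after routing, if any).
#' @param sep Separator between fields (default `" | "`).
#' @param labels Optional named character vector overriding the rendered
#'   field labels; by default the feature name with underscores as spaces
#'   and an initial capital, and `narrative` rendered as
#'   `"Clinical narrative"`.
#' @return A list with `text` (the rendered string) and `spans` (tibble:
#'   `feature`, `start`, `end`, 1-based inclusive character positions of
#'   the rendered value).
#' @export
render_all_text <- function(record, schema = feature_schema(),
                            sep = " | ", labels = NULL) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  feats <- c(names(schema$tabular_features), schema$text_features)
  pieces <- character(length(feats))
  vals <- character(length(feats))
  for (k in seq_along(feats)) {
    f <- feats[k]
    v <- record[[f]]
    vals[k] <- if (is.numeric(v)) format(v, trim = TRUE, digits = 15)
               else as.character(v)
    if (is.na(vals[k])) vals[k] <- ""
    pieces[k] <- paste0(field_label(f, labels), ": ", vals[k])
  }
  text <- paste(pieces, collapse = sep)
  starts <- integer(length(feats))
  pos <- 1L
  for (k in seq_along(feats)) {
    label_len <- nchar(paste0(field_label(feats[k], labels), ": "))
    starts[k] <- pos + label_len
    pos <- pos + nchar(pieces[k]) + nchar(sep)
  }
  spans <- tibble::tibble(
    feature = feats, start = starts,
    end = starts + nchar(vals) - 1L
  )
  list(text = text, spans = spans)
}

field_label <- function(f, labels = NULL) {
  if (!is.null(labels) && f %in% names(labels)) return(labels[[f]])
  if (f == "narrative") return("Clinical narrative")
  sub("^(.)", "\\U\\1", gsub("_", " ", f), perl = TRUE)
}

#' Weighted sum of two probability pairs
#'
#' The Weighted-Ensemble combination rule: `w * p_text + (1 - w) * p_tab`,
#' elementwise on the probability scale.
#'
#' @param p_text,p_tab Probability vectors/matrices (rows summing to 1).
#' @param w Text-model weight in \[0, 1\].
#' @return Combined probabilities, same shape as the inputs.
#' @export
#' @examples
#' predict_weighted(c(0.8, 0.2), c(0.4, 0.6), w = 0.5)
predict_weighted <- function(p_text, p_tab, w) {
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1) {
    stop("configuration error: w must be a single value in [0, 1]",
         call. = FALSE)
  }
  w * p_text + (1 - w) * p_tab
}

#' Build a Weighted-Ensemble predictor
#'
#' Combines separately trained text and tabular models: the prediction is
#' `w * p_text + (1 - w) * p_tab`. The text model reads the clinical
#' narrative conjoined with any routed high-cardinality features rendered
#' through the All-Text template; the tabular model reads the remaining
#' (non-routed) tabular features.
#'
#' @param text_model,tab_model Fitted predictors.
#' @param w Text-model weight; the reference grid is 0.25, 0.50, 0.75.
#' @param schema A (routed) [feature_schema()].
#' @return Predictor of class `weighted_ensemble`.
#' @export
weighted_ensemble <- function(text_model, tab_model, w,
                              schema = feature_schema()) {
  if (w < 0 || w > 1) stop("configuration error: w outside [0, 1]",
                           call. = FALSE)
  structure(
    list(text_model = text_model, tab_model = tab_model, w = w,
         schema = schema, modality = "combined", method = "weighted"),
    class = c("weighted_ensemble", "mmshap_predictor")
  )
}

# Text-side input of an ensemble: routed features rendered with the
# template, conjoined with the free-text features.
text_side_input <- function(records, schema) {
  routed <- setdiff(schema$text_features, "narrative")
  if (length(routed) == 0L) return(records$narrative)
  vapply(seq_len(nrow(records)), function(i) {
    parts <- vapply(routed, function(f) {
      paste0(field_label(f), ": ", as.character(records[[f]][i]))
    }, "")
    paste(c(parts, paste0("Clinical narrative: ",
                          records$narrative[i])), collapse = " | ")
  }, "")
}

#' @export
predict_proba.weighted_ensemble <- function(object, newdata, ...) {
  p_text <- predict_proba(object$text_model,
                          text_side_input(newdata, object$schema))
  p_tab <- predict_proba(
    object$tab_model,
    newdata[, names(object$schema$tabular_features), drop = FALSE])
  predict_weighted(p_text, p_tab, object$w)
}

#' Build an All-Text predictor
#'
#' Serialises the whole record through [render_all_text()] and feeds the
#' string to a text model; the only architecture in which tabular values
#' pass through the language model.
#'
#' @param text_model Fitted text predictor.
#' @param schema A [feature_schema()].
#' @return Predictor of class `all_text_model`.
#' @export
all_text_model <- function(text_model, schema = feature_schema()) {
  structure(
    list(text_model = text_model, schema = schema, modality = "combined",
         method = "all_text"),
    class = c("all_text_model", "mmshap_predictor")
  )
}

#' @export
predict_proba.all_text_model <- function(object, newdata, ...) {
  texts <- vapply(seq_len(nrow(newdata)), function(i) {
    render_all_text(newdata[i, ], object$schema)$text
  }, "")
  predict_proba(object$text_model, texts)
}

#' Fit a Stack-Ensemble
#'
#' Trains a gradient-boosting meta-model on the tabular features plus the
#' positive-class probabilities of the already-fitted text and tabular
#' base models, using the held-out validation examples only (never the
#' base models' training data), then composes all three into one
#' predictor. Meta input dimensionality is `|tabular features| + 2`.
#'
#' @param text_model,tab_model Base predictors fitted on the training
#'   split.
#' @param validation Labelled validation examples (record columns plus
#'   `label`), disjoint from the base training data.
#' @param schema A (routed) [feature_schema()].
#' @param nrounds,max_depth,eta Meta-model boosting hyper-parameters.
#' @param seed Integer seed.
#' @return Predictor of class `stack_ensemble`.
#' @export
fit_stack <- function(text_model, tab_model, validation,
                      schema = feature_schema(), nrounds = 50L,
                      max_depth = 3L, eta = 0.3, seed = 1L) {
  if (nrow(validation) == 0L) stop("empty validation set", call. = FALSE)
  meta_df <- stack_meta_frame(validation, text_model, tab_model, schema)
  meta <- fit_tab_model(meta_df, validation$label, nrounds = nrounds,
                        max_depth = max_depth, eta = eta, seed = seed)
  structure(
    list(text_model = text_model, tab_model = tab_model, meta_model = meta,
         schema = schema, modality = "combined", method = "stack"),
    class = c("stack_ensemble", "mmshap_predictor")
  )
}

stack_meta_frame <- function(records, text_model, tab_model, schema) {
  tab_cols <- names(schema$tabular_features)
  p_text <- predict_proba(text_model, text_side_input(records, schema))
  p_tab <- predict_proba(tab_model, records[, tab_cols, drop = FALSE])
  out <- records[, tab_cols, drop = FALSE]
  out$.p_text <- p_text[, 2L]
  out$.p_tab <- p_tab[, 2L]
  out
}

#' @export
predict_proba.stack_ensemble <- function(object, newdata, ...) {
  meta_df <- stack_meta_frame(newdata, object$text_model,
                              object$tab_model, object$schema)
  predict_proba(object$meta_model, meta_df)
}

#' Evaluate a predictor on labelled examples
#'
#' Computes the binary F1 score (positive class = `"dead"` by default),
#' accuracy and the 2x2 confusion matrix.
#'
#' @param predictor A fitted predictor.
#' @param examples Labelled example tibble with record columns + `label`.
#' @param positive Positive class for F1 (default `"dead"`).
#' @return An `eval_report` list: `f1`, `accuracy`, `n`, `confusion`
#'   (2x2 matrix, truth in rows).
#' @export
evaluate <- function(predictor, examples, positive = "dead") {
  stopifnot(nrow(examples) > 0L, "label" %in% names(examples))
  p <- predict_proba(predictor, examples)
  pred <- colnames(p)[max.col(p, ties.method = "first")]
  truth <- as.character(examples$label)
  classes <- colnames(p)
  confusion <- table(factor(truth, classes), factor(pred, classes))
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  structure(
    list(f1 = f1, accuracy = mean(truth == pred), n = length(truth),
         confusion = unclass(confusion), positive = positive),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "\n")
  cat("  F1 (positive =", x$positive, "):", round(x$f1, 4), "\n")
  cat("  accuracy:", round(x$accuracy, 4), "\n")
  print(x$confusion)
  invisible(x)
}
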