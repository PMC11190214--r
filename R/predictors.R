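#' Predict class probabilities
#'
#' Generic prediction surface shared by every model in the package. All
#' methods return a numeric matrix with one row per input and one column
#' per label (columns named, rows summing to 1).
#'
#' @param object A fitted predictor.
#' @param newdata Model input; the accepted form depends on the modality:
#'   text models take a character vector of narratives or a list of
#'   pre-tokenized word-piece vectors, tabular models a data frame of
#'   feature columns, ensembles a record tibble.
#' @param ... Method-specific arguments.
#' @return Numeric matrix, rows = inputs, columns = labels.
#' @export
predict_proba <- function(object, newdata, ...) {
  UseMethod("predict_proba")
}

proba_matrix <- function(p_pos, labels) {
  m <- cbind(1 - p_pos, p_pos)
  colnames(m) <- labels
  m
}

as_token_lists <- function(newdata, tokenizer) {
  if (is.list(newdata) && !is.data.frame(newdata)) return(newdata)
  if (is.data.frame(newdata)) newdata <- newdata$narrative
  tokenizer(newdata)
}

#' Fixture text classifier: logistic regression over word-piece counts
#'
#' A deterministic stand-in for a fine-tuned language model, with a
#' documented closed form so exact Shapley values can be verified by brute
#' force: the positive-class logit is
#' `intercept + sum over tokens of weight[token] * count[token]`.
#' Tokens absent from `weights` — including the `"[MASK]"` token — carry
#' weight zero, so masking a word-piece removes exactly its contribution.
#'
#' @param weights Named numeric vector of per-word-piece log-odds towards
#'   the positive (second) label.
#' @param intercept Base log-odds (empty narrative -> `plogis(intercept)`).
#' @param labels Length-2 label vector, positive class second.
#' @param tokenizer A [wordpiece_tokenizer()] used when raw text is given.
#' @return Predictor of class `text_logit_model`.
#' @export
#' @examples
#' m <- fixture_text_model(c(collapse = 2, playful = -1))
#' predict_proba(m, "bright alert playful")
fixture_text_model <- function(weights, intercept = 0,
                               labels = c("alive", "dead"),
                               tokenizer = wordpiece_tokenizer()) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            length(labels) == 2L)
  structure(
    list(weights = weights, intercept = intercept, labels = labels,
         tokenizer = tokenizer, modality = "text"),
    class = c("text_logit_model", "mmshap_predictor")
  )
}

#' @export
predict_proba.text_logit_model <- function(object, newdata, ...) {
  toks <- as_token_lists(newdata, object$tokenizer)
  w <- object$weights
  logit <- vapply(toks, function(tk) {
    if (length(tk) == 0L) return(object$intercept)
    object$intercept + sum(w[match(tk, names(w))], na.rm = TRUE)
  }, numeric(1))
  proba_matrix(stats::plogis(logit), object$labels)
}

#' Fit a text classifier on labelled narratives
#'
#' Ridge-penalised logistic regression over word-piece counts via glmnet,
#' at a small fixed penalty so perfectly separable vocabularies fit
#' stably and deterministically. Returns the same `text_logit_model`
#' closed form as [fixture_text_model()], with learned weights.
#'
#' @param narratives Character vector.
#' @param labels Character/factor vector of two classes; the
#'   alphabetically second class is the positive one.
#' @param lambda Ridge penalty (default 1e-2).
#' @param seed Integer seed (glmnet here is deterministic; kept for the
#'   trainer interface).
#' @param tokenizer A [wordpiece_tokenizer()].
#' @return A fitted `text_logit_model`.
#' @export
fit_text_model <- function(narratives, labels, lambda = 1e-2, seed = 1L,
                           tokenizer = wordpiece_tokenizer()) {
  classes <- sort(unique(as.character(labels)))
  stopifnot(length(classes) == 2L)
  toks <- tokenizer(narratives)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) < 2L) stop("degenerate vocabulary", call. = FALSE)
  ij <- purrr::imap(toks, function(tk, i) {
    if (length(tk) == 0L) return(NULL)
    tab <- table(match(tk, vocab))
    cbind(i = i, j = as.integer(names(tab)), x = as.numeric(tab))
  })
  ij <- do.call(rbind, ij)
  X <- Matrix::sparseMatrix(i = ij[, "i"], j = ij[, "j"], x = ij[, "x"],
                            dims = c(length(toks), length(vocab)))
  y <- as.integer(as.character(labels) == classes[2L])
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  beta <- as.numeric(fit$beta[, 1L])
  names(beta) <- vocab
  fixture_text_model(weights = beta[beta != 0],
                     intercept = as.numeric(fit$a0[1L]),
                     labels = classes, tokenizer = tokenizer)
}

#' Fixture tabular classifier: logistic regression with given weights
#'
#' Deterministic closed-form tabular stand-in: positive-class logit is
#' `intercept + sum_j weight_j * x_j` over numeric features, plus optional
#' per-level offsets for categorical features. Used to make exact Shapley
#' values computable by hand in tests.
#'
#' @param weights Named numeric vector over numeric feature columns.
#' @param intercept Base log-odds.
#' @param cat_weights Optional named list: feature -> named numeric vector
#'   of per-level log-odds offsets (unknown levels contribute 0).
#' @param labels Length-2 label vector, positive class second.
#' @return Predictor of class `tab_logit_model`.
#' @export
fixture_tab_model <- function(weights, intercept = 0, cat_weights = list(),
                              labels = c("alive", "dead")) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  structure(
    list(weights = weights, intercept = intercept,
         cat_weights = cat_weights, labels = labels, modality = "tabular"),
    class = c("tab_logit_model", "mmshap_predictor")
  )
}

#' @export
predict_proba.tab_logit_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  logit <- rep(object$intercept, nrow(newdata))
  for (f in names(object$weights)) {
    if (f %in% names(newdata)) {
      logit <- logit + object$weights[[f]] * as.numeric(newdata[[f]])
    }
  }
  for (f in names(object$cat_weights)) {
    if (f %in% names(newdata)) {
      wv <- object$cat_weights[[f]]
      add <- wv[match(as.character(newdata[[f]]), names(wv))]
      add[is.na(add)] <- 0
      logit <- logit + add
    }
  }
  proba_matrix(stats::plogis(logit), object$labels)
}

#' Gradient-boosting tabular classifier
#'
#' The package's trained tabular (and stack meta-) model: an xgboost
#' gradient-boosting classifier over the schema's tabular features.
#' Categorical features are integer-coded against the levels seen at
#' training time (unseen levels map to 0).
#'
#' @param data Data frame of training rows.
#' @param labels Two-class label vector; alphabetically second = positive.
#' @param features Character vector of feature columns (default: all
#'   columns of `data`).
#' @param nrounds,max_depth,eta Boosting hyper-parameters.
#' @param seed Integer seed.
#' @return Predictor of class `tab_boost_model`.
#' @export
fit_tab_model <- function(data, labels, features = names(data),
                          nrounds = 50L, max_depth = 3L, eta = 0.3,
                          seed = 1L) {
  classes <- sort(unique(as.character(labels)))
  stopifnot(length(classes) == 2L)
  enc <- encode_levels(data[, features, drop = FALSE])
  X <- encode_matrix(data[, features, drop = FALSE], enc)
  y <- as.integer(as.character(labels) == classes[2L])
  booster <- withr_seed(seed, {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
      nrounds = nrounds
    )
  })
  structure(
    list(booster = booster, encoding = enc, features = features,
         labels = classes, modality = "tabular"),
    class = c("tab_boost_model", "mmshap_predictor")
  )
}

encode_levels <- function(df) {
  lapply(df, function(col) {
    if (is.numeric(col)) NULL else sort(unique(as.character(col)))
  })
}

encode_matrix <- function(df, enc) {
  cols <- lapply(names(enc), function(f) {
    col <- df[[f]]
    if (is.null(enc[[f]])) as.numeric(col)
    else {
      idx <- match(as.character(col), enc[[f]])
      idx[is.na(idx)] <- 0L
      as.numeric(idx)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(enc)
  m
}

#' @export
predict_proba.tab_boost_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  X <- encode_matrix(newdata[, object$features, drop = FALSE],
                     object$encoding)
  p <- stats::predict(object$booster,
                      xgboost::xgb.DMatrix(X, nthread = 1L))
  proba_matrix(as.numeric(p), object$labels)
}
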