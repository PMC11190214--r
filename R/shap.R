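#' Masking specification for coalition games
#'
#' Declares how absent players are simulated, per modality: an absent text
#' word-piece is replaced in place by `mask_token`; an absent tabular
#' feature takes values from rows of a background dataset, and the
#' coalition's model value is the mean prediction over those rows
#' (empirical integration over the marginal distribution). The same
#' `n_background_samples` rows, drawn once per explanation with the given
#' seed, are reused across all coalitions, which removes background noise
#' from coalition contrasts.
#'
#' @param background Tibble of tabular rows (record-like) to sample from.
#'   May be `NULL` only when no tabular player exists.
#' @param mask_token Replacement token for absent word-pieces
#'   (default `"[MASK]"`).
#' @param n_background_samples Rows drawn (with replacement) from
#'   `background`; default 50.
#' @param seed Integer seed for the background draw.
#' @return A `masking_spec` list.
#' @export
masking_spec <- function(background = NULL, mask_token = "[MASK]",
                         n_background_samples = 50L, seed = 1L) {
  stopifnot(n_background_samples >= 1L)
  structure(
    list(background = background, mask_token = mask_token,
         n_background_samples = as.integer(n_background_samples),
         seed = as.integer(seed)),
    class = "masking_spec"
  )
}

#' Decompose a record into attribution players for a given model
#'
#' Builds the `explain_instance`: the ordered list of players — one per
#' (non-routed) tabular feature, one per word-piece of each text feature —
#' together with the token segments needed to assemble model-ready inputs
#' under any coalition. Template scaffolding (rendered field labels,
#' separators) is kept as ever-present non-player tokens. For the All-Text
#' architecture, tabular values rendered into the template remain
#' tabular-typed players whose masking replaces their whole rendered span.
#'
#' @param record One-row record tibble.
#' @param model The predictor to be explained (determines which modalities
#'   have players).
#' @param schema A (routed) [feature_schema()]; defaults to the model's
#'   own schema when it carries one.
#' @return An `explain_instance` with a `players` tibble
#'   (`player_id`, `modality`, `feature`, `token`, `position`, `value`).
#' @export
build_instance <- function(record, model, schema = model_schema(model)) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  tokenizer <- model_tokenizer(model)
  method <- model_method(model)
  tab_feats <- if (method %in% c("text_only")) character(0)
               else names(schema$tabular_features)
  text_feats <- if (method %in% c("tab_only")) character(0)
                else schema$text_features

  players <- list()
  segments <- list()
  next_id <- 1L
  add_player <- function(modality, feature, token = NA_character_,
                         position = NA_integer_, value = NA_character_) {
    players[[next_id]] <<- tibble::tibble(
      player_id = next_id, modality = modality, feature = feature,
      token = token, position = position, value = value)
    next_id <<- next_id + 1L
    next_id - 1L
  }
  scaffold <- function(tokens) {
    if (length(tokens) > 0L) {
      segments[[length(segments) + 1L]] <<-
        list(type = "scaffold", tokens = tokens)
    }
  }
  tok1 <- function(x) tokenizer(x)[[1]]

  if (method == "all_text") {
    feats <- c(tab_feats, text_feats)
    for (k in seq_along(feats)) {
      f <- feats[k]
      if (k > 1L) scaffold("|")
      scaffold(tok1(paste0(field_label(f), ":")))
      if (f %in% tab_feats) {
        val <- render_value(record[[f]])
        pid <- add_player("tabular", f, value = val)
        segments[[length(segments) + 1L]] <- list(
          type = "tabvalue", feature = f, player_id = pid,
          tokens = tok1(val))
      } else {
        toks <- tok1(as.character(record[[f]]))
        ids <- integer(length(toks))
        for (j in seq_along(toks)) {
          ids[j] <- add_player("text", f, token = toks[j], position = j)
        }
        segments[[length(segments) + 1L]] <- list(
          type = "text", feature = f, tokens = toks, player_ids = ids)
      }
    }
  } else {
    for (f in tab_feats) {
      add_player("tabular", f, value = render_value(record[[f]]))
    }
    bare <- identical(text_feats, "narrative")
    for (k in seq_along(text_feats)) {
      f <- text_feats[k]
      if (!bare) {
        if (k > 1L) scaffold("|")
        scaffold(tok1(paste0(field_label(f), ":")))
      }
      toks <- tok1(as.character(record[[f]]))
      ids <- integer(length(toks))
      for (j in seq_along(toks)) {
        ids[j] <- add_player("text", f, token = toks[j], position = j)
      }
      if (length(toks) > 0L) {
        segments[[length(segments) + 1L]] <- list(
          type = "text", feature = f, tokens = toks, player_ids = ids)
      }
    }
  }

  players <- if (length(players) > 0L) dplyr::bind_rows(players)
             else tibble::tibble(player_id = integer(0),
                                 modality = character(0),
                                 feature = character(0),
                                 token = character(0),
                                 position = integer(0),
                                 value = character(0))
  structure(
    list(players = players, segments = segments,
         tabular = record[, intersect(tab_feats, names(record)),
                          drop = FALSE],
         record = record, schema = schema, method = method),
    class = "explain_instance"
  )
}

render_value <- function(v) {
  if (is.numeric(v)) format(v, trim = TRUE, digits = 15) else as.character(v)
}

model_schema <- function(model) {
  if (!is.null(model$schema)) model$schema else feature_schema()
}

model_tokenizer <- function(model) {
  for (slot in c("tokenizer", "text_model")) {
    if (!is.null(model[[slot]])) {
      if (slot == "tokenizer") return(model$tokenizer)
      if (!is.null(model$text_model$tokenizer))
        return(model$text_model$tokenizer)
    }
  }
  wordpiece_tokenizer()
}

model_method <- function(model) {
  if (!is.null(model$method)) return(model$method)
  switch(model$modality,
         text = "text_only", tabular = "tab_only",
         stop("cannot infer combination method for this model",
              call. = FALSE))
}

#' @export
print.explain_instance <- function(x, ...) {
  cat("<explain_instance>", nrow(x$players), "players (",
      sum(x$players$modality == "tabular"), "tabular,",
      sum(x$players$modality == "text"), "text ) —", x$method, "\n")
  invisible(x)
}

# --- coalition input assembly -----------------------------------------------

# Token sequences for a batch of coalitions. M: logical matrix
# (n_coalitions x n_players). For "tabvalue" segments, value tokens of
# absent players are replaced by the tokens of bg_values[[feature]][[b]]
# (one token list per background row); b selects the background row.
assemble_tokens <- function(instance, M, mask_token, bg_tokens = NULL,
                            b = NULL) {
  lapply(seq_len(nrow(M)), function(r) {
    member <- M[r, ]
    out <- lapply(instance$segments, function(seg) {
      switch(seg$type,
        scaffold = seg$tokens,
        text = ifelse(member[seg$player_ids], seg$tokens, mask_token),
        tabvalue = if (member[seg$player_id]) seg$tokens
                   else bg_tokens[[seg$feature]][[b]]
      )
    })
    unlist(out, use.names = FALSE)
  })
}

# Expanded tabular frame: one block of n_bg rows per coalition; present
# players keep the record's value, absent players take the background
# row's value. Returns list(df, coalition = block index per row).
expand_tabular <- function(instance, M, bg_sample) {
  tab_players <- instance$players[instance$players$modality == "tabular", ]
  B <- nrow(bg_sample)
  nc <- nrow(M)
  df <- bg_sample[rep(seq_len(B), times = nc), , drop = FALSE]
  for (k in seq_len(nrow(tab_players))) {
    f <- tab_players$feature[k]
    present <- rep(M[, tab_players$player_id[k]], each = B)
    df[[f]][present] <- instance$record[[f]]
  }
  list(df = df, coalition = rep(seq_len(nc), each = B))
}

draw_background <- function(instance, spec) {
  tab_players <- instance$players[instance$players$modality == "tabular", ]
  if (nrow(tab_players) == 0L) return(NULL)
  if (is.null(spec$background) || nrow(spec$background) == 0L) {
    stop("empty background dataset with tabular players present",
         call. = FALSE)
  }
  need <- unique(tab_players$feature)
  missing <- setdiff(need, names(spec$background))
  if (length(missing) > 0L) {
    stop("background lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- withr_seed(spec$seed, {
    sample.int(nrow(spec$background), spec$n_background_samples,
               replace = TRUE)
  })
  spec$background[idx, need, drop = FALSE]
}

#' Materialise the model-ready inputs for one coalition
#'
#' Reference masking semantics: players inside the coalition are left
#' untouched; absent text players are replaced in place by the mask token
#' (tokenization boundaries preserved — no re-tokenization); absent
#' tabular players take values from each of the background-sample rows in
#' turn. The model value of the coalition is the mean prediction over the
#' returned inputs. A full coalition yields a single unmodified input.
#'
#' @param instance An [build_instance()] result.
#' @param coalition Integer vector of player ids treated as present.
#' @param spec A [masking_spec()].
#' @return List of model-ready inputs, each a list with `tokens`
#'   (character vector or `NULL`) and `tabular` (one-row tibble or
#'   `NULL`).
#' @export
mask <- function(instance, coalition, spec) {
  stopifnot(inherits(instance, "explain_instance"))
  ids <- instance$players$player_id
  if (length(setdiff(coalition, ids)) > 0L) {
    stop("coalition contains unknown player ids", call. = FALSE)
  }
  member <- matrix(ids %in% coalition, nrow = 1L)
  tab_players <- instance$players$modality == "tabular"
  has_tab <- any(tab_players)
  has_text <- length(instance$segments) > 0L
  needs_bg <- has_tab && any(tab_players & !member[1, ])

  bg_sample <- if (needs_bg) draw_background(instance, spec) else NULL
  B <- if (is.null(bg_sample)) 1L else nrow(bg_sample)
  bg_tokens <- background_token_table(instance, bg_sample)

  lapply(seq_len(B), function(b) {
    tokens <- if (has_text) {
      assemble_tokens(instance, member, spec$mask_token, bg_tokens, b)[[1]]
    } else NULL
    tabular <- if (has_tab) {
      row <- instance$tabular
      if (!is.null(bg_sample)) {
        for (k in which(tab_players & !member[1, ])) {
          f <- instance$players$feature[k]
          row[[f]] <- bg_sample[[f]][b]
        }
      }
      row
    } else NULL
    list(tokens = tokens, tabular = tabular)
  })
}

background_token_table <- function(instance, bg_sample) {
  if (is.null(bg_sample)) return(NULL)
  tv <- Filter(function(s) s$type == "tabvalue", instance$segments)
  if (length(tv) == 0L) return(NULL)
  tokenizer <- wordpiece_tokenizer()
  feats <- unique(vapply(tv, function(s) s$feature, ""))
  out <- lapply(feats, function(f) {
    lapply(seq_len(nrow(bg_sample)), function(b) {
      tokenizer(render_value(bg_sample[[f]][b]))[[1]]
    })
  })
  stats::setNames(out, feats)
}

# --- coalition value functions ----------------------------------------------

# Returns function(M) -> matrix (nrow(M) x 2 labels) for the joint game of
# `model` on `instance`, with background rows fixed by `spec`.
coalition_value_fun <- function(model, instance, spec) {
  tab_players <- instance$players$modality == "tabular"
  has_tab <- any(tab_players)
  bg_sample <- if (has_tab) draw_background(instance, spec) else NULL
  bg_tokens <- background_token_table(instance, bg_sample)
  method <- instance$method
  labels <- model_labels(model)

  average_blocks <- function(p, coalition) {
    sums <- rowsum(p, coalition)
    sums / as.numeric(table(coalition))
  }

  if (method == "text_only") {
    function(M) {
      toks <- assemble_tokens(instance, M, spec$mask_token)
      predict_proba(model, toks)
    }
  } else if (method == "tab_only") {
    function(M) {
      ex <- expand_tabular(instance, M, bg_sample)
      average_blocks(predict_proba(model, ex$df), ex$coalition)
    }
  } else if (method == "all_text") {
    function(M) {
      B <- nrow(bg_sample)
      preds <- vector("list", B)
      for (b in seq_len(B)) {
        toks <- assemble_tokens(instance, M, spec$mask_token, bg_tokens, b)
        preds[[b]] <- predict_proba(model$text_model, toks)
      }
      Reduce(`+`, preds) / B
    }
  } else if (method == "weighted") {
    function(M) {
      toks <- assemble_tokens(instance, M[, , drop = FALSE],
                              spec$mask_token)
      p_text <- predict_proba(model$text_model, toks)
      ex <- expand_tabular(instance, M, bg_sample)
      p_tab <- average_blocks(predict_proba(model$tab_model, ex$df),
                              ex$coalition)
      predict_weighted(p_text, p_tab, model$w)
    }
  } else if (method == "stack") {
    function(M) {
      toks <- assemble_tokens(instance, M, spec$mask_token)
      p_text <- predict_proba(model$text_model, toks)
      ex <- expand_tabular(instance, M, bg_sample)
      B <- nrow(bg_sample)
      meta_df <- ex$df
      p_tab_rows <- predict_proba(model$tab_model, ex$df)
      meta_df$.p_text <- rep(p_text[, 2L], each = B)
      meta_df$.p_tab <- p_tab_rows[, 2L]
      average_blocks(predict_proba(model$meta_model, meta_df),
                     ex$coalition)
    }
  } else {
    stop("unsupported method: ", method, call. = FALSE)
  }
}

model_labels <- function(model) {
  if (!is.null(model$labels)) return(model$labels)
  if (!is.null(model$text_model)) return(model$text_model$labels)
  c("alive", "dead")
}

membership_matrix <- function(masks, n) {
  M <- outer(masks, 2^(seq_len(n) - 1L),
             function(m, b) floor(m / b) %% 2 == 1)
  matrix(as.logical(M), nrow = length(masks))
}

# --- Shapley computation ----------------------------------------------------

new_shap_explanation <- function(players, values, se, base_values,
                                 model_output, estimator, n_permutations,
                                 seed, labels) {
  colnames(values) <- labels
  if (!is.null(se)) colnames(se) <- labels
  structure(
    list(players = players, values = values, se = se,
         base_values = stats::setNames(as.numeric(base_values), labels),
         model_output = stats::setNames(as.numeric(model_output), labels),
         estimator = estimator, n_permutations = n_permutations,
         seed = seed, labels = labels),
    class = "shap_explanation"
  )
}

#' Exact Shapley values by full coalition enumeration
#'
#' Evaluates the model value function on all `2^n` coalitions and computes
#' the classic Shapley value for every player and label. Satisfies the
#' efficiency, symmetry, dummy and linearity axioms to floating tolerance.
#' Refuses player counts above `exact_limit` (the enumeration doubles per
#' player); use [estimate_shapley()] beyond it.
#'
#' @param value_fun Function mapping a logical membership matrix
#'   (coalitions x players) to a value matrix (coalitions x labels).
#' @param n_players Number of players.
#' @param labels Label names for the value columns.
#' @param players Optional players tibble to attach.
#' @param exact_limit Maximum player count (default 12).
#' @return A `shap_explanation`.
#' @export
#' @examples
#' # two-player game v(1)=1, v(2)=2, v(12)=4: phi = (1.5, 2.5)
#' vf <- function(M) cbind(M[, 1] * 1 + M[, 2] * 2 + M[, 1] * M[, 2] * 1)
#' exact_shapley(vf, 2, labels = "v")$values
exact_shapley <- function(value_fun, n_players, labels = c("alive", "dead"),
                          players = NULL, exact_limit = 12L) {
  if (n_players > exact_limit) {
    stop("player count ", n_players, " exceeds the exact enumeration ",
         "limit (", exact_limit, "); use estimate_shapley()",
         call. = FALSE)
  }
  masks <- seq(0, 2^n_players - 1)
  M <- membership_matrix(masks, n_players)
  v <- value_fun(M)
  if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
  size <- rowSums(M)
  s <- 0:(n_players - 1)
  wt <- exp(lfactorial(s) + lfactorial(n_players - 1 - s) -
              lfactorial(n_players))
  phi <- matrix(0, n_players, ncol(v))
  for (i in seq_len(n_players)) {
    without <- which(!M[, i])
    with_i <- without + 2^(i - 1)
    dw <- wt[size[without] + 1L]
    phi[i, ] <- colSums(dw * (v[with_i, , drop = FALSE] -
                                v[without, , drop = FALSE]))
  }
  new_shap_explanation(
    players = players %||% default_players(n_players),
    values = phi, se = NULL, base_values = v[1L, ],
    model_output = v[2^n_players, ], estimator = "exact",
    n_permutations = NA_integer_, seed = NA_integer_,
    labels = labels[seq_len(ncol(v))]
  )
}

default_players <- function(n) {
  tibble::tibble(player_id = seq_len(n), modality = NA_character_,
                 feature = paste0("player_", seq_len(n)),
                 token = NA_character_, position = NA_integer_,
                 value = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation-sampling Shapley estimator
#'
#' Unbiased sampling estimator: for each sampled permutation the players
#' are added one by one and each player's marginal contribution recorded,
#' once in forward and once in reversed order (antithetic pair); the two
#' traversals are averaged into one sample per permutation, from which the
#' per-player standard errors are computed. Because every traversal
#' telescopes from the empty to the full coalition, the estimate satisfies
#' the efficiency axiom exactly. Deterministic given `seed`.
#'
#' @inheritParams exact_shapley
#' @param n_permutations Number of sampled permutations (>= 1).
#' @param seed Integer seed.
#' @return A `shap_explanation` with per-player `se`.
#' @export
estimate_shapley <- function(value_fun, n_players, n_permutations = 200L,
                             seed = 1L, labels = c("alive", "dead"),
                             players = NULL) {
  stopifnot(n_permutations >= 1L)
  n <- n_players
  P <- withr_seed(seed, {
    out <- matrix(0L, n_permutations, n)
    for (i in seq_len(n_permutations)) out[i, ] <- sample.int(n)
    out
  })
  Pf <- P
  Pr <- P[, rev(seq_len(n)), drop = FALSE]
  if (n <= 46L) {
    # coalitions as integer bitmasks in doubles (exact below 2^53)
    bit <- 2^(seq_len(n) - 1)
    path_of <- function(Pm) {
      # masks after adding the first k players of each permutation; col 1 = 0
      added <- matrix(bit[t(Pm)], nrow = n)      # n x n_perm, column-major
      cums <- apply(added, 2L, cumsum)
      if (is.null(dim(cums))) cums <- matrix(cums, nrow = 1L)
      cbind(0, t(cums))                          # n_perm x (n+1)
    }
    If <- path_of(Pf)
    Ir <- path_of(Pr)
    all_masks <- sort(unique(c(as.numeric(If), as.numeric(Ir))))
    M <- membership_matrix(all_masks, n)
    lookup <- function(I) matrix(match(as.numeric(I), all_masks), nrow(I))
    Jf <- lookup(If)
    Jr <- lookup(Ir)
  } else {
    # beyond 46 players a bitmask no longer fits a double exactly;
    # deduplicate path coalitions by membership-string keys instead
    m0 <- n_permutations
    path_rows <- function(Pm) {
      rows <- matrix(FALSE, m0 * (n + 1L), n)
      for (p in seq_len(m0)) {
        base <- (p - 1L) * (n + 1L)
        memb <- logical(n)
        for (k in seq_len(n)) {
          memb[Pm[p, k]] <- TRUE
          rows[base + k + 1L, ] <- memb
        }
      }
      rows
    }
    Rf <- path_rows(Pf)
    Rr <- path_rows(Pr)
    keys <- c(apply(Rf, 1L, paste, collapse = ""),
              apply(Rr, 1L, paste, collapse = ""))
    ukeys <- unique(keys)
    M <- rbind(Rf, Rr)[match(ukeys, keys), , drop = FALSE]
    idx <- match(keys, ukeys)
    half <- nrow(Rf)
    Jf <- matrix(idx[seq_len(half)], m0, n + 1L, byrow = TRUE)
    Jr <- matrix(idx[half + seq_len(half)], m0, n + 1L, byrow = TRUE)
  }
  v <- value_fun(M)
  if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
  L <- ncol(v)
  m <- n_permutations
  phi <- matrix(0, n, L)
  se <- matrix(0, n, L)
  reorder <- function(C, Pm) {
    # C[p, k] is the contribution of the k-th added player Pm[p, k];
    # scatter into player order
    S <- matrix(NA_real_, m, n)
    S[cbind(rep(seq_len(m), times = n), as.vector(Pm))] <- as.vector(C)
    S
  }
  for (l in seq_len(L)) {
    vf <- matrix(v[Jf, l], m)
    vr <- matrix(v[Jr, l], m)
    Cf <- vf[, -1L, drop = FALSE] - vf[, -(n + 1L), drop = FALSE]
    Cr <- vr[, -1L, drop = FALSE] - vr[, -(n + 1L), drop = FALSE]
    S <- (reorder(Cf, Pf) + reorder(Cr, Pr)) / 2
    phi[, l] <- colMeans(S)
    se[, l] <- if (m > 1L) apply(S, 2L, stats::sd) / sqrt(m) else NA_real_
  }
  base <- v[Jf[1L, 1L], ]
  full <- v[Jf[1L, n + 1L], ]
  new_shap_explanation(
    players = players %||% default_players(n), values = phi, se = se,
    base_values = base, model_output = full, estimator = "sampled",
    n_permutations = as.integer(n_permutations), seed = as.integer(seed),
    labels = labels[seq_len(L)]
  )
}

#' Explain a text-tabular model prediction with multimodal Shapley values
#'
#' Builds the joint coalition game over the union of the model's text and
#' tabular players for one record — masking text players with the mask
#' token and integrating absent tabular players over the background sample
#' — and solves it exactly (full enumeration) when the player count is
#' within `exact_limit`, otherwise with the permutation-sampling
#' estimator. Works for any of the five combination architectures as well
#' as single-modality models.
#'
#' @param model A fitted predictor (ensemble or single-modality).
#' @param record One-row record tibble.
#' @param spec A [masking_spec()]; its background must cover the model's
#'   tabular features.
#' @param estimator `"auto"` (default), `"exact"` or `"sampled"`.
#' @param n_permutations Permutations for the sampling estimator.
#' @param seed Seed for the sampling estimator.
#' @param exact_limit Maximum player count for exact enumeration.
#' @param schema Optional schema override.
#' @return A `shap_explanation`: per-player, per-label attributions,
#'   base values (empty-coalition model output) and estimator metadata.
#' @export
explain_ensemble <- function(model, record, spec,
                             estimator = c("auto", "exact", "sampled"),
                             n_permutations = 200L, seed = 1L,
                             exact_limit = 12L,
                             schema = model_schema(model)) {
  estimator <- match.arg(estimator)
  instance <- build_instance(record, model, schema)
  n <- nrow(instance$players)
  if (n == 0L) stop("instance has no players", call. = FALSE)
  vf <- coalition_value_fun(model, instance, spec)
  labels <- model_labels(model)
  use_exact <- switch(estimator,
                      exact = TRUE, sampled = FALSE,
                      auto = n <= exact_limit)
  out <- if (use_exact) {
    exact_shapley(vf, n, labels = labels, players = instance$players,
                  exact_limit = exact_limit)
  } else {
    estimate_shapley(vf, n, n_permutations = n_permutations, seed = seed,
                     labels = labels, players = instance$players)
  }
  out$instance <- instance
  out
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat("<shap_explanation>", nrow(x$players), "players x",
      length(x$labels), "labels,", x$estimator, "\n")
  cat("  base:", paste(sprintf("%s=%.4f", x$labels, x$base_values),
                       collapse = " "), "\n")
  cat("  output:", paste(sprintf("%s=%.4f", x$labels, x$model_output),
                         collapse = " "), "\n")
  top <- order(-abs(x$values[, ncol(x$values)]))[seq_len(min(5, nrow(x$players)))]
  for (i in top) {
    nm <- if (!is.na(x$players$token[i])) {
      paste0(x$players$feature[i], "/", x$players$token[i])
    } else x$players$feature[i]
    cat(sprintf("  %-28s %+ .4f\n", nm, x$values[i, ncol(x$values)]))
  }
  invisible(x)
}

#' Efficiency gap of an explanation
#'
#' Per label: `base_value + sum(values) - model_output`; zero (to
#' tolerance) for any valid Shapley explanation.
#'
#' @param explanation A `shap_explanation`.
#' @return Named numeric vector, one gap per label.
#' @export
efficiency_gap <- function(explanation) {
  explanation$base_values + colSums(explanation$values) -
    explanation$model_output
}
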