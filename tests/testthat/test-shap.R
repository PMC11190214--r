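test_that("exact Shapley solves small games correctly", {
  # v({})=0, v({1})=1, v({2})=2, v({1,2})=4: phi = (1.5, 2.5)
  vf <- function(M) cbind(M[, 1] * 1 + M[, 2] * 2 + (M[, 1] & M[, 2]) * 1)
  e <- exact_shapley(vf, 2, labels = "v")
  expect_equal(as.numeric(e$values), c(1.5, 2.5))
  expect_equal(as.numeric(e$base_values), 0)

  # dummy player: player 3 never changes the value
  vf3 <- function(M) cbind(2 * M[, 1] + 7 * M[, 2])
  e3 <- exact_shapley(vf3, 3, labels = "v")
  expect_equal(as.numeric(e3$values), c(2, 7, 0))

  # symmetric players receive equal values
  vfs <- function(M) cbind((M[, 1] + M[, 2])^2)
  es <- exact_shapley(vfs, 2, labels = "v")
  expect_equal(es$values[1, ], es$values[2, ])

  expect_error(exact_shapley(vf, 20, labels = "v"),
               "estimate_shapley")
})

test_that("exact engine agrees with an ordering-enumeration oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    coef <- stats::rnorm(2^n)
    vf <- function(M) {
      # arbitrary nonlinear game: value indexed by coalition bitmask
      idx <- as.integer(M %*% 2^(seq_len(ncol(M)) - 1)) + 1L
      cbind(coef[idx])
    }
    fast <- exact_shapley(vf, n, labels = "v")$values
    slow <- brute_shapley(vf, n)
    expect_equal(unname(fast), slow, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("the permutation estimator is unbiased, efficient and seeded", {
  vf <- function(M) cbind(3 * M[, 1] - 2 * M[, 2] + M[, 1] * M[, 3])
  est <- estimate_shapley(vf, 3, n_permutations = 400, seed = 5,
                          labels = "v")
  exact <- exact_shapley(vf, 3, labels = "v")
  expect_true(all(abs(est$values - exact$values) <=
                    3 * pmax(est$se, 1e-12) + 1e-12))
  # efficiency holds exactly: every traversal telescopes
  expect_lt(max(abs(efficiency_gap(est))), 1e-12)
  # determinism
  est2 <- estimate_shapley(vf, 3, n_permutations = 400, seed = 5,
                           labels = "v")
  expect_identical(est$values, est2$values)

  # one-player game: estimator is exactly v(full) - v(empty)
  vf1 <- function(M) cbind(ifelse(M[, 1], 0.9, 0.1))
  e1 <- estimate_shapley(vf1, 1, n_permutations = 3, seed = 1,
                         labels = "v")
  expect_equal(as.numeric(e1$values), 0.8)
})

test_that("the estimator stays exact and efficient beyond bitmask range", {
  # above 46 players coalitions cannot be held in a double bitmask; the
  # key-based path must still be exact on an additive game (any single
  # traversal of a linear game already yields the true values)
  w <- seq(0.01, 0.5, length.out = 55)
  vf <- function(M) cbind(as.numeric(M %*% w))
  e <- estimate_shapley(vf, 55, n_permutations = 20, seed = 3,
                        labels = "v")
  expect_lt(max(abs(e$values - w)), 1e-12)
  expect_lt(max(abs(efficiency_gap(e))), 1e-12)
  e2 <- estimate_shapley(vf, 55, n_permutations = 20, seed = 3,
                         labels = "v")
  expect_identical(e$values, e2$values)
})

test_that("estimator error shrinks like 1/sqrt(n) on an 8-player game", {
  set.seed(31)
  coef <- stats::rnorm(2^8)
  vf <- function(M) {
    idx <- as.integer(M %*% 2^(seq_len(ncol(M)) - 1)) + 1L
    cbind(coef[idx])
  }
  exact <- exact_shapley(vf, 8, labels = "v")$values
  err <- vapply(c(50, 200, 800), function(np) {
    errs <- vapply(1:5, function(s) {
      est <- estimate_shapley(vf, 8, n_permutations = np, seed = s,
                              labels = "v")
      sqrt(mean((est$values - exact)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  # quadrupling the budget roughly halves the error
  slope <- log(err[1] / err[3]) / log(sqrt(800 / 50))
  expect_gt(slope, 0.6)
  expect_lt(slope, 1.5)
})

test_that("instances decompose records into the expected players", {
  # default schema: 9 general + 21 ICD tabular players + narrative pieces
  rec <- make_record("a1", 0L,
                     narrative = "bright alert eating well nad bar coat good teeth good weight stable")
  tb <- fixture_tab_model(c(age_at_consult = 0.1))
  tm <- small_text_model()
  we <- weighted_ensemble(tm, tb, 0.5, schema = feature_schema())
  inst <- build_instance(rec, we)
  expect_equal(sum(inst$players$modality == "tabular"), 30L)
  expect_equal(sum(inst$players$modality == "text"), 12L)

  # empty narrative: zero text players
  inst0 <- build_instance(make_record("a1", 0L, narrative = ""), we)
  expect_equal(sum(inst0$players$modality == "text"), 0L)

  # routed categorical feature becomes word-piece players of that feature
  sch <- feature_schema(tabular_features = c(age_at_consult = "numeric",
                                             breed = "categorical"))
  sch$tabular_features <- sch$tabular_features["age_at_consult"]
  sch$text_features <- c("breed", "narrative")
  rec2 <- make_record("a1", 0L, narrative = "", breed = "border collie")
  inst2 <- build_instance(rec2, weighted_ensemble(tm, tb, 0.5, sch))
  breed_players <- inst2$players[inst2$players$feature == "breed", ]
  expect_equal(nrow(breed_players), 2L)
  expect_equal(breed_players$token, c("border", "collie"))
  expect_true(all(breed_players$modality == "text"))
})

test_that("masking replaces only players outside the coalition", {
  sch <- small_schema()
  we <- weighted_ensemble(small_text_model(), small_tab_model(), 0.5,
                          schema = sch)
  rec <- small_record("bright alert collapse")
  inst <- build_instance(rec, we)
  spec <- masking_spec(small_background(), n_background_samples = 5,
                       seed = 3)

  # full coalition: single unmodified input
  full <- mask(inst, inst$players$player_id, spec)
  expect_length(full, 1L)
  expect_identical(full[[1]]$tokens, c("bright", "alert", "collapse"))
  expect_identical(full[[1]]$tabular$age_at_consult, rec$age_at_consult)

  # drop one text player: its piece becomes [MASK], all else byte-identical
  drop_tok <- inst$players$player_id[inst$players$token %in% "alert"]
  m1 <- mask(inst, setdiff(inst$players$player_id, drop_tok), spec)
  expect_length(m1, 1L)
  expect_identical(m1[[1]]$tokens, c("bright", "[MASK]", "collapse"))
  expect_identical(m1[[1]]$tabular, full[[1]]$tabular)

  # drop one tabular player: background values flow in, coalition intact
  drop_age <- inst$players$player_id[inst$players$feature == "age_at_consult"]
  m2 <- mask(inst, setdiff(inst$players$player_id, drop_age), spec)
  expect_length(m2, 5L)
  for (b in seq_along(m2)) {
    expect_identical(m2[[b]]$tokens, full[[1]]$tokens)
    expect_identical(m2[[b]]$tabular$icd_skin, rec$icd_skin)
  }
  bg_ages <- vapply(m2, function(x) x$tabular$age_at_consult, numeric(1))
  expect_true(all(bg_ages %in% spec$background$age_at_consult))

  expect_error(mask(inst, 999L, spec), "unknown player")
  empty_spec <- masking_spec(NULL)
  expect_error(mask(inst, integer(0), empty_spec), "background")
})

test_that("coalition values equal the mean prediction over masked inputs", {
  sch <- small_schema()
  tm <- small_text_model()
  tb <- small_tab_model()
  we <- weighted_ensemble(tm, tb, 0.5, schema = sch)
  rec <- small_record()
  inst <- build_instance(rec, we)
  spec <- masking_spec(small_background(), n_background_samples = 7,
                       seed = 9)
  vf <- mmshap:::coalition_value_fun(we, inst, spec)

  # hand-average over the background rows for a coalition missing age
  ids <- inst$players$player_id
  coalition <- setdiff(ids, ids[inst$players$feature == "age_at_consult"])
  M <- matrix(ids %in% coalition, nrow = 1)
  batch_val <- vf(M)
  inputs <- mask(inst, coalition, spec)
  preds <- t(vapply(inputs, function(inp) {
    p_text <- predict_proba(tm, list(inp$tokens))
    p_tab <- predict_proba(tb, inp$tabular)
    as.numeric(predict_weighted(p_text, p_tab, 0.5))
  }, numeric(2)))
  expect_equal(as.numeric(batch_val), colMeans(preds), tolerance = 1e-12)

  # a 2-row background: value is the mean of predictions at the 2 ages
  bg2 <- tibble::tibble(age_at_consult = c(2, 10), icd_skin = 0L,
                        icd_neoplasms = 0L)
  spec2 <- masking_spec(bg2, n_background_samples = 2, seed = 1)
  vf2 <- mmshap:::coalition_value_fun(we, inst, spec2)
  v2 <- vf2(M)
  bg_rows <- mmshap:::draw_background(inst, spec2)
  manual <- vapply(bg_rows$age_at_consult, function(a) {
    r <- rec
    r$age_at_consult <- a
    predict_proba(we, r)[, 2]
  }, numeric(1))
  expect_equal(unname(v2[, 2]), mean(manual), tolerance = 1e-12)
})

test_that("explanations satisfy efficiency, antisymmetry and monotone sanity", {
  sch <- small_schema()
  we <- weighted_ensemble(small_text_model(), small_tab_model(), 0.5,
                          schema = sch)
  spec <- masking_spec(small_background(), n_background_samples = 6,
                       seed = 2)
  set.seed(17)
  narrs <- c("bright alert", "collapse", "tumour found collapse",
             "nad", "bright bright collapse")
  for (nv in narrs) {
    rec <- small_record(nv, age = stats::runif(1, 1, 14))
    ex <- explain_ensemble(we, rec, spec)
    expect_lt(max(abs(efficiency_gap(ex))), 1e-9)
    expect_lt(max(abs(ex$values[, 1] + ex$values[, 2])), 1e-9)
    expect_equal(as.numeric(ex$model_output),
                 as.numeric(predict_proba(we, rec)), tolerance = 1e-12)
    # the model is monotone increasing in "collapse": its players never
    # pull towards alive
    ids <- which(ex$players$token %in% "collapse")
    if (length(ids) > 0) expect_true(all(ex$values[ids, "dead"] >= -1e-12))
  }
})

test_that("weighted ensembles obey Shapley linearity across modalities", {
  sch <- small_schema()
  tm <- small_text_model()
  tb <- small_tab_model()
  spec <- masking_spec(small_background(), n_background_samples = 6,
                       seed = 4)
  rec <- small_record("bright alert collapse")
  ext <- explain_ensemble(tm, rec, spec, schema = sch)
  exb <- explain_ensemble(tb, rec, spec, schema = sch)
  n_text <- nrow(ext$players)
  n_tab <- nrow(exb$players)
  for (w in c(0.25, 0.5, 0.75)) {
    we <- weighted_ensemble(tm, tb, w, schema = sch)
    joint <- explain_ensemble(we, rec, spec)
    # joint player order: tabular block then text block
    padded <- w * rbind(matrix(0, n_tab, 2), ext$values) +
      (1 - w) * rbind(exb$values, matrix(0, n_text, 2))
    expect_lt(max(abs(joint$values - padded)), 1e-9)
  }
})

test_that("stack and all-text joint games are efficient and consistent", {
  sch <- small_schema()
  tm <- small_text_model()
  tb <- small_tab_model()
  spec <- masking_spec(small_background(), n_background_samples = 5,
                       seed = 6)
  rec <- small_record("collapse tumour")

  cohort <- generate_cohort(generator_config(n_animals = 60, seed = 31))
  val <- cohort$records[!duplicated(cohort$records$animal_id), ][1:40, ]
  val$label <- rep(c("alive", "dead"), 20)
  st <- fit_stack(tm, tb, val, schema = sch, nrounds = 10, seed = 1)
  ex_st <- explain_ensemble(st, rec, spec)
  expect_lt(max(abs(efficiency_gap(ex_st))), 1e-9)
  expect_equal(as.numeric(ex_st$model_output),
               as.numeric(predict_proba(st, rec)), tolerance = 1e-12)

  at <- all_text_model(tm, schema = sch)
  ex_at <- explain_ensemble(at, rec, spec)
  expect_lt(max(abs(efficiency_gap(ex_at))), 1e-9)
  expect_equal(as.numeric(ex_at$model_output),
               as.numeric(predict_proba(at, rec)), tolerance = 1e-12)
  # tabular values rendered in the template stay tabular-typed players
  expect_equal(sum(ex_at$players$modality == "tabular"), 3L)

  # w = 0: text players carry no attribution
  w0 <- explain_ensemble(weighted_ensemble(tm, tb, 0, schema = sch), rec,
                         spec)
  text_rows <- w0$players$modality == "text"
  expect_lt(max(abs(w0$values[text_rows, ])), 1e-12)
})

test_that("tidy and glance expose explanation content", {
  sch <- small_schema()
  we <- weighted_ensemble(small_text_model(), small_tab_model(), 0.5,
                          schema = sch)
  spec <- masking_spec(small_background(), n_background_samples = 4,
                       seed = 2)
  ex <- explain_ensemble(we, small_record(), spec)
  td <- tidy(ex)
  expect_equal(nrow(td), 2 * nrow(ex$players))
  expect_setequal(unique(td$label), c("alive", "dead"))
  expect_equal(td$value[td$label == "alive" & td$token %in% "collapse"],
               unname(ex$values[ex$players$token %in% "collapse", "alive"]))
  gl <- glance(ex)
  expect_equal(gl$n_players, nrow(ex$players))
  expect_lt(gl$max_abs_efficiency_gap, 1e-9)
})
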