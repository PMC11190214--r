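# Build a shap_explanation directly from a players tibble + value matrix.
manual_explanation <- function(features, modality, values, tokens = NULL,
                               positions = NULL, labels = c("alive", "dead")) {
  n <- length(features)
  players <- tibble::tibble(
    player_id = seq_len(n), modality = modality, feature = features,
    token = tokens %||% rep(NA_character_, n),
    position = positions %||% rep(NA_integer_, n),
    value = rep(NA_character_, n))
  mmshap:::new_shap_explanation(
    players = players, values = values, se = NULL,
    base_values = c(0.5, 0.5), model_output = 0.5 + colSums(values),
    estimator = "exact", n_permutations = NA_integer_, seed = NA_integer_,
    labels = labels)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("phi aggregation sums within feature, then |.|, then across labels", {
  # two pieces of one feature: alive (0.1, -0.05), dead (-0.1, 0.05)
  ex <- manual_explanation(
    c("narrative", "narrative"), c("text", "text"),
    cbind(c(0.1, -0.05), c(-0.1, 0.05)),
    tokens = c("a", "b"), positions = 1:2)
  expect_equal(phi_aggregate(ex)$phi, 0.10)

  # all-zero players give phi 0
  ex0 <- manual_explanation("age", "tabular", cbind(0, 0))
  expect_equal(phi_aggregate(ex0)$phi, 0)

  # single tabular player alive 0.3 / dead -0.3 gives phi 0.6
  ex1 <- manual_explanation("age", "tabular", cbind(0.3, -0.3))
  expect_equal(phi_aggregate(ex1)$phi, 0.6)
})

test_that("phi obeys the triangle inequality and label antisymmetry identity", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    feats <- sample(c("f1", "f2", "f3"), n, replace = TRUE)
    va <- stats::rnorm(n, sd = 0.2)
    ex <- manual_explanation(feats, rep("text", n), cbind(va, -va),
                             tokens = letters[1:n], positions = 1:n)
    phi <- phi_aggregate(ex)
    bound <- tibble::tibble(feature = feats, b = 2 * abs(va)) |>
      dplyr::group_by(feature) |>
      dplyr::summarise(b = sum(b))
    merged <- dplyr::left_join(phi, bound, by = "feature")
    expect_true(all(merged$phi <= merged$b + 1e-12))
    expect_true(all(merged$phi >= -1e-12))
    # probability-pair models: phi = 2 |sum of alive values|
    alive_sum <- tibble::tibble(feature = feats, v = va) |>
      dplyr::group_by(feature) |>
      dplyr::summarise(v = sum(v))
    merged2 <- dplyr::left_join(phi, alive_sum, by = "feature")
    expect_equal(merged2$phi, 2 * abs(merged2$v))
  }
})

test_that("importance proportions are normalised means of |phi|", {
  tbl <- tibble::tibble(
    instance = c("i1", "i1", "i2", "i2"),
    feature = c("A", "B", "A", "B"),
    phi = c(2, 1, 4, 1))
  s <- summarise_importance(tbl)
  expect_equal(s$proportion[s$feature == "A"], 0.75)
  expect_equal(s$proportion[s$feature == "B"], 0.25)
  expect_equal(sum(s$proportion), 1, tolerance = 1e-12)

  single <- summarise_importance(tibble::tibble(
    instance = "i1", feature = "A", phi = 3))
  expect_equal(single$proportion, 1)

  # permuting instances changes nothing
  perm <- summarise_importance(tbl[c(3, 1, 4, 2), ])
  expect_equal(s, perm)
  expect_error(summarise_importance(tbl[0, ]), "empty")
})

test_that("kendall_tau matches the pairwise formula and its symmetries", {
  expect_equal(kendall_tau(c(3, 2, 1), c(3, 2, 1)), 1)
  expect_equal(kendall_tau(c(3, 2, 1), c(1, 2, 3)), -1)
  # ranks (1,2,3) vs (1,3,2): pairs (1,2)+(1,3) concordant, (2,3) discordant
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  expect_error(kendall_tau(1, 1), ">= 2 features")

  set.seed(5)
  for (rep in 1:20) {
    a <- stats::rnorm(8)
    b <- stats::rnorm(8)
    # antisymmetric under reversing one ranking
    expect_equal(kendall_tau(a, -b), -kendall_tau(a, b))
    # invariant under strictly monotone transforms
    expect_equal(kendall_tau(exp(a), b), kendall_tau(a, b))
    expect_equal(kendall_tau(a, rank(b)), kendall_tau(a, b))
    # agrees with the standard tie-free implementation (tau-a == tau-b)
    expect_equal(kendall_tau(a, b),
                 stats::cor(a, b, method = "kendall"), tolerance = 1e-12)
  }
})

test_that("compare_rankings summarises per-instance tau", {
  set.seed(9)
  phi_a <- tidyr::expand_grid(instance = paste0("i", 1:20),
                              feature = paste0("f", 1:6))
  phi_a$phi <- stats::runif(nrow(phi_a))
  self <- compare_rankings(phi_a, phi_a)
  expect_equal(self$mean, 1)
  expect_equal(self$sd, 0)
  expect_equal(self$n, 20)

  phi_b <- phi_a
  phi_b$phi <- stats::runif(nrow(phi_b))
  cmp <- compare_rankings(phi_a, phi_b)
  expect_true(all(abs(cmp$per_instance$tau) <= 1))
  expect_equal(cmp$mean, mean(cmp$per_instance$tau))
  expect_equal(cmp$sd, stats::sd(cmp$per_instance$tau))

  # pooled total equals recomputation from the raw per-instance values
  pooled <- pool_comparisons(list(self, cmp))
  all_tau <- c(self$per_instance$tau, cmp$per_instance$tau)
  expect_equal(pooled$mean, mean(all_tau))
  expect_equal(pooled$sd, stats::sd(all_tau))
  expect_equal(pooled$n, 40)

  misaligned <- phi_b[phi_b$instance != "i1", ]
  expect_error(compare_rankings(phi_a, misaligned), "misaligned")
})

test_that("importance differences feed a Kruskal-Wallis comparison", {
  base <- tidyr::expand_grid(instance = paste0("i", 1:30),
                             feature = c("narrative", "age"))
  # identical constant differences across groups: H = 0
  const <- dplyr::bind_rows(
    dplyr::mutate(base, group = "m1"),
    dplyr::mutate(base, group = "m2"))
  const$phi <- ifelse(const$feature == "narrative", 0.6, 0.2)
  const$instance <- paste(const$instance, const$group)
  d0 <- importance_difference(const, "narrative", "age")
  expect_equal(d0$h, 0)
  expect_equal(d0$differences$diff, rep(0.4, nrow(d0$differences)))

  # disjoint supports: decisive rejection
  set.seed(13)
  shift <- const
  shift$phi <- ifelse(shift$feature == "narrative",
                      stats::runif(nrow(shift)) +
                        ifelse(shift$group == "m2", 5, 0), 0)
  d1 <- importance_difference(shift, "narrative", "age")
  expect_lt(d1$p_value, 0.001)
  expect_gt(d1$epsilon_sq, 0.5)

  expect_error(importance_difference(const[const$feature == "age", ],
                                     "narrative", "age"), "present")
})

test_that("null rejection rate of the H test is near the nominal level", {
  set.seed(99)
  reject <- vapply(1:200, function(r) {
    tbl <- tidyr::expand_grid(instance = paste0("i", r, "_", 1:40),
                              feature = c("x", "y"))
    tbl$group <- rep(c("g1", "g2"), each = nrow(tbl) / 2)
    tbl$phi <- ifelse(tbl$feature == "x", stats::rnorm(nrow(tbl)), 0)
    importance_difference(tbl, "x", "y")$p_value < 0.05
  }, logical(1))
  # binomial(200, 0.05): 3 sd band around 10 rejections
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("top_phrases merges pieces into words and cohesive phrases", {
  # "eu"/"##thanasia"-style continuation pieces always merge, with summed value
  ex <- manual_explanation(
    rep("narrative", 3), rep("text", 3),
    cbind(c(-0.2, -0.1, 0.05), c(0.2, 0.1, -0.05)),
    tokens = c("euth", "##anasia", "given"), positions = 1:3)
  out <- top_phrases(ex, k = 10)
  expect_true("euthanasia" %in% out$phrase)
  expect_equal(out$mean_value[out$phrase == "euthanasia"][1], -0.3)

  # adjacent same-sign words above the cohesion threshold merge into a phrase
  ex2 <- manual_explanation(
    rep("narrative", 4), rep("text", 4),
    cbind(c(-0.2, -0.25, 0.3, 0.01), c(0.2, 0.25, -0.3, -0.01)),
    tokens = c("slowing", "down", "bright", "alert"), positions = 1:4)
  out2 <- top_phrases(ex2, grouping_threshold = 0.4, k = 10)
  expect_true("slowing down" %in% out2$phrase)      # ratio 0.8, same sign
  expect_false("bright alert" %in% out2$phrase)     # ratio 0.03 below 0.4
  expect_true(all(c("bright", "alert") %in% out2$phrase))

  # repeated strings are averaged; tabular values render "feature = value"
  exa <- manual_explanation("narrative", "text", cbind(0.2, -0.2),
                            tokens = "nad", positions = 1L)
  exb <- manual_explanation("narrative", "text", cbind(0.4, -0.4),
                            tokens = "nad", positions = 1L)
  out3 <- top_phrases(list(exa, exb), k = 3)
  expect_equal(out3$mean_value[out3$phrase == "nad"][1], 0.3)
  expect_equal(out3$n_occurrences[out3$phrase == "nad"][1], 2L)

  ext <- manual_explanation("age_at_consult", "tabular", cbind(0.25, -0.25))
  ext$players$value <- "0.61"
  out4 <- top_phrases(ext, k = 2)
  expect_true("age_at_consult = 0.61" %in% out4$phrase)

  # k beyond the distinct items returns everything; exclusion drops features
  expect_lte(nrow(top_phrases(exa, k = 50)), 2)
  out5 <- top_phrases(list(ext, exa), k = 5,
                      exclude_features = "age_at_consult")
  expect_false(any(grepl("age_at_consult", out5$phrase)))
})

test_that("phrase ranking follows the alive-positive signed convention", {
  ex <- manual_explanation(
    rep("narrative", 2), rep("text", 2),
    cbind(c(0.5, -0.4), c(-0.5, 0.4)),
    tokens = c("playful", "tumour"), positions = 1:2)
  out <- top_phrases(ex, k = 1)
  expect_equal(out$phrase[out$direction == "top"], "playful")
  expect_equal(out$phrase[out$direction == "bottom"], "tumour")
  expect_gt(out$mean_value[out$direction == "top"], 0)
  expect_lt(out$mean_value[out$direction == "bottom"], 0)
})
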