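#' The mortality-term extraction pattern
#'
#' Alternation of substrings whose presence in a narrative flags a possible
#' declaration of death or euthanasia. Matching is case-insensitive
#' substring alternation with no word boundaries, so `"quality"` also
#' matches `"qualities"`.
#'
#' @return The pattern string.
#' @export
mortality_pattern <- function() {
  "euth|dead|died|pts|put to sleep|pento|doa|crem|burial|bury|qol|quality|ashes|scatter|casket"
}

#' Flag narratives that mention death or euthanasia
#'
#' Scans each narrative for the alternatives of `pattern` and reports which
#' fired. `matched` is `TRUE` iff at least one alternative matched;
#' `matched_terms` lists every alternative with at least one hit, in
#' pattern order.
#'
#' @param narratives Character vector (or a record tibble with a
#'   `narrative` column).
#' @param pattern Alternation pattern; default [mortality_pattern()].
#' @param word_boundaries Require the alternative to match at word
#'   boundaries (default `FALSE`: plain substring semantics).
#' @return Tibble with `narrative`, `matched`, `matched_terms`
#'   (list-column). If a record tibble was supplied, its `animal_id` and
#'   `consult_index` columns are carried through.
#' @export
#' @examples
#' flag_mortality("owner elected euthanasia today")$matched_terms[[1]]
flag_mortality <- function(narratives, pattern = mortality_pattern(),
                           word_boundaries = FALSE) {
  carry <- NULL
  if (is.data.frame(narratives)) {
    carry <- narratives[intersect(c("animal_id", "consult_index"),
                                  names(narratives))]
    narratives <- narratives$narrative
  }
  alts <- strsplit(pattern, "|", fixed = TRUE)[[1]]
  if (length(alts) == 0L || any(!nzchar(alts))) {
    stop("configuration error: empty alternative in pattern", call. = FALSE)
  }
  ok <- tryCatch({grepl(pattern, "x", ignore.case = TRUE); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("configuration error: pattern does not compile", call. = FALSE)

  low <- tolower(ifelse(is.na(narratives), "", narratives))
  hit <- vapply(alts, function(a) {
    if (word_boundaries) {
      grepl(paste0("\\b", a, "\\b"), low)
    } else {
      grepl(a, low, fixed = TRUE)
    }
  }, logical(length(low)))
  hit <- matrix(hit, nrow = length(low))
  terms <- apply(hit, 1L, function(h) alts[h], simplify = FALSE)
  out <- tibble::tibble(
    narrative = narratives,
    matched = rowSums(hit) > 0L,
    matched_terms = terms
  )
  if (!is.null(carry) && ncol(carry) > 0L) out <- dplyr::bind_cols(carry, out)
  out
}

#' Propagate death-declaration labels with a teacher-student step
#'
#' Trains a student classifier on a small labelled seed set of narratives
#' and applies it to the unlabelled corpus, the semi-supervised pattern
#' used to scale a manually validated definition to a full dataset. The
#' default student is a ridge-penalised logistic regression over word-piece
#' counts ([fit_text_model()]); any factory returning a fitted predictor
#' with a [predict_proba()] method can be substituted.
#'
#' @param seed_labelled Tibble with `narrative` and `label` columns; both
#'   classes must be present.
#' @param unlabelled Character vector of narratives to label.
#' @param student_trainer Function `(narratives, labels, seed) -> predictor`.
#' @param seed Integer seed.
#' @return Tibble with `narrative`, `label` (predicted), and
#'   `prob` (probability of the positive = second sorted class).
#' @export
teacher_student_propagate <- function(seed_labelled, unlabelled,
                                      student_trainer = NULL, seed = 1L) {
  stopifnot(is.data.frame(seed_labelled),
            all(c("narrative", "label") %in% names(seed_labelled)))
  classes <- sort(unique(seed_labelled$label))
  if (length(classes) < 2L) {
    stop("degenerate training: seed set contains a single class",
         call. = FALSE)
  }
  if (length(classes) > 2L) {
    stop("teacher-student labelling is binary; got ", length(classes),
         " classes", call. = FALSE)
  }
  if (length(unlabelled) == 0L) {
    return(tibble::tibble(narrative = character(0), label = character(0),
                          prob = numeric(0)))
  }
  if (is.null(student_trainer)) {
    student_trainer <- function(narratives, labels, seed) {
      fit_text_model(narratives, labels, seed = seed)
    }
  }
  student <- student_trainer(seed_labelled$narrative, seed_labelled$label,
                             seed)
  p <- predict_proba(student, unlabelled)
  pos <- colnames(p)[2L]
  tibble::tibble(
    narrative = unlabelled,
    label = ifelse(p[, 2L] >= 0.5, pos, colnames(p)[1L]),
    prob = as.numeric(p[, 2L])
  )
}

#' Cohort-construction configuration
#'
#' @param balance_ratio Controls sampled per case; default 1 (balanced).
#' @param test_fraction Fraction of examples held out for testing
#'   (default 0.20, the 80:20 convention).
#' @param validation_fraction Fraction carved out of the training portion
#'   for meta-model fitting; default 0.10.
#' @param seed Integer seed for control sampling and splitting.
#' @param regex_pattern Mortality pattern; default [mortality_pattern()].
#' @param required_fields Fields whose absence makes a record incomplete.
#' @param control_consult `"latest"` (default) or `"random"`: which
#'   consultation of an alive animal becomes its control example.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(balance_ratio = 1, test_fraction = 0.2,
                          validation_fraction = 0.1, seed = 1L,
                          regex_pattern = mortality_pattern(),
                          required_fields = default_required_fields(),
                          control_consult = c("latest", "random")) {
  stopifnot(balance_ratio > 0, test_fraction > 0, test_fraction < 1,
            validation_fraction >= 0, validation_fraction < 1,
            test_fraction + validation_fraction < 1)
  structure(
    list(balance_ratio = balance_ratio, test_fraction = test_fraction,
         validation_fraction = validation_fraction, seed = as.integer(seed),
         regex_pattern = regex_pattern, required_fields = required_fields,
         control_consult = match.arg(control_consult)),
    class = "cohort_config"
  )
}

#' Assemble a balanced case-control mortality cohort
#'
#' Implements the case-control construction around a declaration-of-death
#' label: the case example for a dying animal is the consultation
#' immediately preceding the declaration; controls are drawn, at
#' `balance_ratio` controls per case, from animals whose latest
#' consultation carries no death label. Exclusions, each counted in the
#' `exclusions` attribute and logged via `message()`:
#' \itemize{
#'   \item `single_narrative`: the death declaration is the animal's only
#'     consultation, so no preceding narrative exists;
#'   \item `incomplete`: the would-be example record has a missing required
#'     field (breed, age, sex or geography by default);
#'   \item `dual_membership`: the animal qualifies as both case and
#'     control (a death flag earlier in a history that continues), removed
#'     from both sides.
#' }
#' Each surviving example's ICD indicator counts are replaced by their
#' cumulative sums over the animal's history up to and including the
#' example consultation, summarising prior clinical history.
#'
#' @param records Record tibble ordered by `consult_index` within animal.
#' @param death_labels Tibble with `animal_id`, `consult_index`, `dead`
#'   (logical): the per-consultation death-declaration labels (from
#'   [flag_mortality()] and/or [teacher_student_propagate()]).
#' @param config A [cohort_config()].
#' @param quiet Suppress the per-rule exclusion log (default `FALSE`).
#' @return Tibble of labelled examples (record columns plus `label`), with
#'   attribute `"exclusions"` (named counts per rule). Use
#'   [split_examples()] to assign train/validation/test.
#' @export
build_case_control <- function(records, death_labels,
                               config = cohort_config(), quiet = FALSE) {
  stopifnot(is.data.frame(records), is.data.frame(death_labels),
            all(c("animal_id", "consult_index", "dead") %in%
                  names(death_labels)))
  if (nrow(records) == 0L) {
    stop("empty cohort: no records supplied", call. = FALSE)
  }
  records <- dplyr::arrange(records, .data$animal_id, .data$consult_index)
  lab <- dplyr::select(death_labels, "animal_id", "consult_index", "dead")
  recs <- dplyr::left_join(records, lab,
                           by = c("animal_id", "consult_index")) |>
    dplyr::mutate(dead = dplyr::coalesce(.data$dead, FALSE))

  excl <- c(single_narrative = 0L, incomplete = 0L, dual_membership = 0L)

  per_animal <- recs |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      first_death = if (any(.data$dead)) min(.data$consult_index[.data$dead])
                    else NA_integer_,
      last_index = max(.data$consult_index),
      last_dead = .data$dead[which.max(.data$consult_index)],
      .groups = "drop"
    )

  case_ids <- per_animal$animal_id[!is.na(per_animal$first_death)]
  control_pool <- per_animal$animal_id[!per_animal$last_dead]

  dual <- intersect(case_ids, control_pool)
  excl["dual_membership"] <- length(dual)
  case_ids <- setdiff(case_ids, dual)
  control_pool <- setdiff(control_pool, dual)

  # case example: consultation immediately preceding the declaration
  incomplete_record <- function(df) {
    apply(is.na(df[, intersect(config$required_fields, names(df)),
                   drop = FALSE]), 1L, any)
  }
  case_rows <- recs |>
    dplyr::inner_join(
      per_animal |>
        dplyr::filter(.data$animal_id %in% case_ids) |>
        dplyr::transmute(.data$animal_id, .data$first_death),
      by = "animal_id") |>
    dplyr::filter(.data$consult_index < .data$first_death) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::slice_max(.data$consult_index, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  n_single <- length(setdiff(case_ids, case_rows$animal_id))
  excl["single_narrative"] <- n_single

  inc <- incomplete_record(case_rows)
  excl["incomplete"] <- excl["incomplete"] + sum(inc)
  case_rows <- case_rows[!inc, ]

  if (nrow(case_rows) == 0L) {
    stop("empty cohort: no cases survive filtering", call. = FALSE)
  }

  # control example: by default the latest consultation, mirroring recency
  control_rows <- recs |>
    dplyr::filter(.data$animal_id %in% control_pool) |>
    dplyr::group_by(.data$animal_id)
  control_rows <- if (config$control_consult == "latest") {
    dplyr::slice_max(control_rows, .data$consult_index, n = 1L,
                     with_ties = FALSE)
  } else {
    dplyr::slice_sample(control_rows, n = 1L)
  }
  control_rows <- dplyr::ungroup(control_rows)
  inc_c <- incomplete_record(control_rows)
  excl["incomplete"] <- excl["incomplete"] + sum(inc_c)
  control_rows <- control_rows[!inc_c, ]

  n_controls <- min(nrow(control_rows),
                    round(config$balance_ratio * nrow(case_rows)))
  picked <- withr_seed(config$seed, {
    sample(control_rows$animal_id, n_controls)
  })
  control_rows <- control_rows[control_rows$animal_id %in% picked, ]

  examples <- dplyr::bind_rows(
    dplyr::mutate(case_rows, label = "dead"),
    dplyr::mutate(control_rows, label = "alive")
  ) |>
    dplyr::select(-dplyr::any_of(c("first_death", "dead")))

  # cumulative ICD history up to and including the example consultation
  cum <- recs |>
    dplyr::filter(.data$animal_id %in% examples$animal_id) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::arrange(.data$consult_index, .by_group = TRUE) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(icd_columns()),
                                cumsum)) |>
    dplyr::ungroup() |>
    dplyr::select("animal_id", "consult_index",
                  dplyr::all_of(icd_columns()))
  examples <- examples |>
    dplyr::select(-dplyr::all_of(icd_columns())) |>
    dplyr::left_join(cum, by = c("animal_id", "consult_index")) |>
    dplyr::select(dplyr::all_of(c(record_columns(), "label")))

  if (!quiet) {
    message("cohort: ", sum(examples$label == "dead"), " cases, ",
            sum(examples$label == "alive"), " controls; excluded ",
            paste(names(excl), excl, sep = "=", collapse = ", "))
  }
  attr(examples, "exclusions") <- excl
  examples
}

#' Assign train / validation / test splits by animal
#'
#' Splits labelled examples with an 80:20-style train:test partition,
#' stratified by label and grouped by animal so no animal straddles
#' splits. Within each label stratum, `floor(fraction * n)` animals go to
#' test and validation and the remainder to train; assignment order is a
#' seeded shuffle, so the same seed reproduces the same split.
#'
#' @param examples Labelled example tibble (from [build_case_control()]).
#' @param config A [cohort_config()] supplying fractions and seed.
#' @return `examples` with a `split` column
#'   (`"train"`/`"validation"`/`"test"`).
#' @export
split_examples <- function(examples, config = cohort_config()) {
  stopifnot("label" %in% names(examples))
  if (nrow(examples) < 3L) {
    stop("fewer examples than splits", call. = FALSE)
  }
  assign_one <- function(ids, seed_offset) {
    n <- length(ids)
    n_test <- floor(config$test_fraction * n)
    n_val <- floor(config$validation_fraction * n)
    ids <- withr_seed(config$seed + seed_offset, sample(ids))
    split <- rep("train", n)
    if (n_test > 0L) split[seq_len(n_test)] <- "test"
    if (n_val > 0L) split[n_test + seq_len(n_val)] <- "validation"
    stats::setNames(split, ids)
  }
  labels <- sort(unique(examples$label))
  out <- character(0)
  for (k in seq_along(labels)) {
    ids <- unique(examples$animal_id[examples$label == labels[k]])
    out <- c(out, assign_one(ids, k))
  }
  examples$split <- unname(out[examples$animal_id])
  examples
}

#' Export a random sample of flagged records for manual review
#'
#' The manual-validation step of regex-based extraction is a human task;
#' this helper draws a seeded random sample of flagged records and writes
#' them to CSV for review.
#'
#' @param records Record tibble.
#' @param flags Output of [flag_mortality()] on the same records.
#' @param path CSV output path.
#' @param n Sample size (default 250).
#' @param seed Integer seed.
#' @return The sampled tibble, invisibly.
#' @export
export_review_sample <- function(records, flags, path, n = 250L, seed = 1L) {
  flagged <- records[flags$matched, , drop = FALSE]
  n <- min(n, nrow(flagged))
  out <- withr_seed(seed, flagged[sample(nrow(flagged), n), ])
  readr::write_csv(out, path, na = "")
  invisible(out)
}
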