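#' Configuration for the synthetic veterinary EHR generator
#'
#' The generator emulates the statistical structure a text-tabular
#' mortality pipeline assumes: per-animal consultation histories with
#' non-decreasing age, 21 ICD indicator counts accumulating over visits,
#' templated clinical-note narratives, terminal narratives for dying
#' animals that contain mortality language matching the extraction regex,
#' and planted signal keywords with known effect directions. Death is
#' generated from a single logistic model, so ground truth is unambiguous:
#' \deqn{P(death) = logistic(qlogis(b) + \beta_{age}(age - \bar a) +
#'   \sum_k \beta_k 1[keyword_k])}
#' where `b` is `baseline_death_rate` (the death probability of an
#' average-age animal with no planted keywords) and \eqn{\bar a} the mean
#' terminal age implied by the age mixture.
#'
#' @param n_animals Number of animals.
#' @param mean_consults Mean extra consultations per animal beyond the
#'   first (Poisson); animals destined to die always have at least one
#'   consultation before the terminal one.
#' @param baseline_death_rate Death probability at average age with no
#'   signal keywords; default 0.15.
#' @param age_effect Log-odds of death per year of age; default 0.25.
#' @param signal_keywords Named numeric vector: keyword -> log-odds effect
#'   on death when present in the pre-terminal narrative. Positive pushes
#'   towards death. Default one strong keyword, `c(collapse = 2.5)`.
#' @param keyword_rate Probability each signal keyword is planted for an
#'   animal; default 0.3.
#' @param mean_narrative_len Mean benign-token count per narrative.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_animals = 500L,
                             mean_consults = 2,
                             baseline_death_rate = 0.15,
                             age_effect = 0.25,
                             signal_keywords = c(collapse = 2.5),
                             keyword_rate = 0.3,
                             mean_narrative_len = 8,
                             seed = 1L) {
  stopifnot(n_animals >= 1, baseline_death_rate > 0, baseline_death_rate < 1,
            is.finite(age_effect), all(is.finite(signal_keywords)),
            keyword_rate >= 0, keyword_rate <= 1)
  structure(
    list(n_animals = as.integer(n_animals), mean_consults = mean_consults,
         baseline_death_rate = baseline_death_rate, age_effect = age_effect,
         signal_keywords = signal_keywords, keyword_rate = keyword_rate,
         mean_narrative_len = mean_narrative_len, seed = as.integer(seed)),
    class = "generator_config"
  )
}

synth_breeds <- function() {
  c("labrador", "cocker spaniel", "border collie", "french bulldog",
    "german shepherd", "staffordshire bull terrier", "jack russell",
    "golden retriever", "springer spaniel", "shih tzu", "chihuahua",
    "dachshund", "pug", "boxer", "beagle", "border terrier", "whippet",
    "lurcher", "greyhound", "rottweiler", "husky", "akita", "poodle",
    "cavapoo", "cockapoo", "labradoodle", "domestic shorthair",
    "domestic longhair", "british shorthair", "ragdoll", "bengal",
    "siamese", "maine coon", "persian", "sphynx", "burmese")
}

synth_regions <- function() {
  c("north west", "north east", "yorkshire", "east midlands",
    "west midlands", "east of england", "london", "south east",
    "south west", "wales", "scotland north", "scotland south",
    "northern ireland", "cumbria", "lancashire", "merseyside",
    "cheshire", "greater manchester", "south yorkshire",
    "west yorkshire", "tyne and wear", "durham", "northumberland",
    "norfolk", "suffolk", "essex", "kent", "surrey", "sussex",
    "hampshire", "dorset", "devon", "cornwall", "somerset")
}

benign_phrases <- function() {
  c("bright and alert", "eating and drinking well", "ce unremarkable",
    "abdo palp nad", "coat good", "teeth good", "hydration normal",
    "booster given", "vaccination given", "wormer given", "nad",
    "bar", "dude normal", "weight stable", "no concerns", "playful",
    "ears fine", "eyes fine", "skin good", "recheck fine",
    "appetite good", "o reports all well", "advised flea check")
}

mortality_phrases <- function() {
  c("owner elected euthanasia today", "pts with pento today",
    "put to sleep at home", "found dead this morning doa",
    "sadly died overnight", "euthanased on qol grounds",
    "discussed quality of life owner elected euthanasia",
    "pts ashes to scatter", "cremation arranged casket chosen",
    "home burial planned")
}

#' Generate a synthetic consultation cohort with known ground truth
#'
#' @param config A [generator_config()].
#' @return A list with `records` (consultation tibble, one row per visit,
#'   in `animal_id`/`consult_index` order) and `truth` (one row per animal:
#'   `animal_id`, `died`, `death_consult_index`, `death_prob`, `log_odds`,
#'   and one logical column per planted signal keyword).
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_animals = 5, seed = 1))
#' cohort$truth
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr_seed(config$seed, {
    n <- config$n_animals
    ids <- sprintf("animal_%05d", seq_len(n))
    species <- sample(c("dog", "cat"), n, replace = TRUE, prob = c(0.6, 0.4))
    breed <- sample(synth_breeds(), n, replace = TRUE)
    region <- sample(synth_regions(), n, replace = TRUE)
    gender <- sample(c("male", "female"), n, replace = TRUE)
    insured <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.35, 0.65))
    neutered <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.7, 0.3))
    practice <- sample(sprintf("prac_%02d", 1:12), n, replace = TRUE)
    premise <- paste0(practice, sample(sprintf("_site_%d", 1:3), n, replace = TRUE))

    # terminal age from a young/old mixture so both regimes exist
    old <- stats::runif(n) < 0.45
    age_final <- ifelse(old, pmin(20, 9 + stats::rgamma(n, 2, 0.55)),
                        pmin(8, stats::rgamma(n, 2.2, 0.9)))
    mean_age <- 0.55 * (2.2 / 0.9) + 0.45 * (9 + 2 / 0.55)

    kw <- names(config$signal_keywords)
    planted <- matrix(stats::runif(n * length(kw)) < config$keyword_rate,
                      nrow = n, dimnames = list(NULL, kw))
    log_odds <- stats::qlogis(config$baseline_death_rate) +
      config$age_effect * (age_final - mean_age) +
      as.numeric(planted %*% config$signal_keywords)
    p_death <- stats::plogis(log_odds)
    died <- stats::runif(n) < p_death
    if (sum(p_death) < 0.5) {
      warning("configuration yields near-zero expected deaths", call. = FALSE)
    }

    n_consults <- 1L + stats::rpois(n, config$mean_consults)
    n_consults[died] <- pmax(2L, n_consults[died])

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      nc <- n_consults[i]
      # ages spaced backwards from the terminal age
      gaps <- sort(stats::runif(nc - 1L, 0.05, 0.6), decreasing = TRUE)
      ages <- round(age_final[i] - c(rev(cumsum(gaps)), 0), 2)
      ages <- pmax(ages, 0.05)
      ages <- cummax(ages)
      narr <- vapply(seq_len(nc), function(j) synth_narrative(config), "")
      # planted keywords live in the narrative the pipeline will extract:
      # the pre-terminal one for dying animals, the final one otherwise
      sig_idx <- if (died[i]) nc - 1L else nc
      for (k in kw[planted[i, ]]) {
        narr[sig_idx] <- paste(narr[sig_idx], "o reports", k)
      }
      if (died[i]) {
        narr[nc] <- sample(mortality_phrases(), 1L)
      }
      icd <- matrix(stats::rpois(nc * 21L, 0.08), nrow = nc)
      rows[[i]] <- tibble::tibble(
        animal_id = ids[i], consult_index = seq_len(nc) - 1L,
        age_at_consult = ages, breed = breed[i], species = species[i],
        gender = gender[i], insured = insured[i], neutered = neutered[i],
        region = region[i], practice_id = practice[i],
        premise_id = premise[i], narrative = narr
      )
      colnames(icd) <- icd_columns()
      rows[[i]] <- dplyr::bind_cols(rows[[i]],
                                    tibble::as_tibble(icd))
    }
    records <- dplyr::bind_rows(rows)[, record_columns()]

    truth <- tibble::tibble(
      animal_id = ids, died = died,
      death_consult_index = ifelse(died, n_consults - 1L, NA_integer_),
      death_prob = p_death, log_odds = log_odds
    )
    for (k in kw) truth[[k]] <- planted[, k]
    list(records = records, truth = truth)
  })
}

synth_narrative <- function(config) {
  len <- max(1L, stats::rpois(1L, config$mean_narrative_len / 3))
  paste(sample(benign_phrases(), len, replace = TRUE), collapse = " ")
}

#' Generate labelled narratives with tunable class separability
#'
#' Produces a binary-labelled narrative set for testing label-propagation
#' components. Each class has a marker token (`"pento"` for the positive
#' class, `"booster"` for the negative); the class marker appears in its
#' own class with probability `0.5 + separability/2` and in the other class
#' with probability `0.5 - separability/2`, so `separability = 1` is
#' perfectly separable by a unigram rule and `separability = 0` carries no
#' signal.
#'
#' @param n Number of narratives.
#' @param separability Real in \[0, 1\].
#' @param seed Integer seed.
#' @return Tibble with `narrative` and `label` (`"pos"`/`"neg"`).
#' @export
generate_labelled_narratives <- function(n, separability = 1, seed = 1L) {
  stopifnot(separability >= 0, separability <= 1, n >= 0)
  if (n == 0L) return(tibble::tibble(narrative = character(0),
                                     label = character(0)))
  withr_seed(seed, {
    label <- sample(c("pos", "neg"), n, replace = TRUE)
    q <- 0.5 + separability / 2
    has_pos_marker <- stats::runif(n) < ifelse(label == "pos", q, 1 - q)
    base <- vapply(seq_len(n), function(i) {
      paste(sample(benign_phrases(), 2L, replace = TRUE), collapse = " ")
    }, "")
    narrative <- ifelse(has_pos_marker, paste(base, "pento given"),
                        paste(base, "booster given"))
    tibble::tibble(narrative = narrative, label = label)
  })
}

# Run code under a local RNG seed without disturbing the global stream.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
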