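# Shared fixtures: a small 3-feature tabular schema, closed-form fixture
# models, and builders for hand-written consultation records.

small_schema <- function() {
  feature_schema(tabular_features = c(
    age_at_consult = "numeric", icd_skin = "numeric",
    icd_neoplasms = "numeric"))
}

small_text_model <- function(weights = c(collapse = 2, bright = -0.5,
                                         tumour = 1.2),
                             intercept = -0.2) {
  fixture_text_model(weights, intercept = intercept)
}

small_tab_model <- function(weights = c(age_at_consult = 0.3,
                                        icd_skin = 0.5,
                                        icd_neoplasms = 1),
                            intercept = -1) {
  fixture_tab_model(weights, intercept = intercept)
}

small_background <- function(n = 40, seed = 99) {
  cohort <- generate_cohort(generator_config(n_animals = n, seed = seed))
  cohort$records[, c("age_at_consult", "icd_skin", "icd_neoplasms")]
}

# One record with a controlled narrative over the small schema's features.
small_record <- function(narrative = "bright alert collapse",
                         age = 6, skin = 1L, neo = 0L) {
  r <- make_record("a1", 0L, narrative = narrative)
  r$age_at_consult <- age
  r$icd_skin <- skin
  r$icd_neoplasms <- neo
  r
}

# A fully populated consultation record row; fields overridable via ...
make_record <- function(animal_id, consult_index, narrative = "nad",
                        age = 5, ...) {
  row <- tibble::tibble(
    animal_id = animal_id, consult_index = as.integer(consult_index),
    age_at_consult = age, breed = "labrador", species = "dog",
    gender = "male", insured = "yes", neutered = "yes",
    region = "north west", practice_id = "p1", premise_id = "p1_s1",
    narrative = narrative
  )
  for (cc in paste0("icd_", icd_indicator_names())) row[[cc]] <- 0L
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row[, mmshap:::record_columns()]
}

# Independent brute-force Shapley oracle: enumerates all orderings and
# averages marginal contributions directly (O(n! * 2^n); tiny n only).
brute_shapley <- function(value_fun, n) {
  perms <- gtools_permutations(n)
  masks <- seq(0, 2^n - 1)
  M <- outer(masks, 2^(seq_len(n) - 1L),
             function(m, b) floor(m / b) %% 2 == 1)
  v <- value_fun(matrix(as.logical(M), nrow = length(masks)))
  if (is.null(dim(v))) v <- matrix(v, ncol = 1)
  phi <- matrix(0, n, ncol(v))
  for (p in seq_len(nrow(perms))) {
    mask <- 0
    for (k in seq_len(n)) {
      i <- perms[p, k]
      with_i <- mask + 2^(i - 1)
      phi[i, ] <- phi[i, ] + (v[with_i + 1, ] - v[mask + 1, ])
      mask <- with_i
    }
  }
  phi / nrow(perms)
}

# All permutations of 1..n without external packages.
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
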