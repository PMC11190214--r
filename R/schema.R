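#' The 21 syndromic disease-indicator names
#'
#' High-level ICD-11-style disease-category indicators recorded per
#' consultation: each counts how many times a consultation touched that
#' body system or condition class. Column names in record tibbles carry the
#' prefix `"icd_"`.
#'
#' @return Character vector of 21 indicator names (without prefix).
#' @export
#' @examples
#' icd_indicator_names()
icd_indicator_names <- function() {
  c(
    "circulatory", "dental", "development", "digestive",
    "endocrine_metabolic", "immune", "neurodevelopment",
    "infectious_parasitic", "skin", "musculoskeletal", "visual",
    "perinatal", "pregnancy", "ears", "blood_forming", "respiratory",
    "injuries", "poisoning_external", "genitourinary", "neoplasms",
    "nervous"
  )
}

icd_columns <- function() paste0("icd_", icd_indicator_names())

#' General (non-indicator) tabular feature names of a consultation record
#' @keywords internal
general_features <- function() {
  c(
    "age_at_consult", "breed", "species", "gender", "insured",
    "neutered", "region", "practice_id", "premise_id"
  )
}

record_columns <- function() {
  c("animal_id", "consult_index", general_features(), icd_columns(),
    "narrative")
}

#' Feature schema for a text-tabular consultation dataset
#'
#' Declares which columns are tabular model inputs (with their kind), which
#' are free-text, the cardinality threshold above which a tabular feature is
#' routed to the text side (see [route_high_cardinality()]), and the two
#' class labels.
#'
#' @param tabular_features Named character vector: names are feature column
#'   names, values are `"numeric"` or `"categorical"`.
#' @param text_features Character vector of free-text feature columns.
#' @param cardinality_threshold Positive integer; a tabular feature with
#'   strictly more unique values than this is treated as text. Default 30.
#' @param label_names Length-2 character vector `(negative, positive)`;
#'   default `c("alive", "dead")`, with `dead` the positive class.
#' @return An object of class `feature_schema`.
#' @export
#' @examples
#' s <- feature_schema()
#' s$cardinality_threshold
feature_schema <- function(tabular_features = default_tabular_features(),
                           text_features = "narrative",
                           cardinality_threshold = 30L,
                           label_names = c("alive", "dead")) {
  stopifnot(
    is.character(tabular_features), !is.null(names(tabular_features)),
    all(tabular_features %in% c("numeric", "categorical")),
    length(label_names) == 2L,
    cardinality_threshold >= 1L
  )
  if (any(names(tabular_features) %in% text_features)) {
    stop("tabular_features and text_features must be disjoint", call. = FALSE)
  }
  structure(
    list(
      tabular_features = tabular_features,
      text_features = text_features,
      cardinality_threshold = as.integer(cardinality_threshold),
      label_names = label_names
    ),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema>\n")
  cat("  tabular:", length(x$tabular_features), "features (",
      sum(x$tabular_features == "numeric"), "numeric,",
      sum(x$tabular_features == "categorical"), "categorical )\n")
  cat("  text:   ", paste(x$text_features, collapse = ", "), "\n")
  cat("  routing threshold: >", x$cardinality_threshold, "unique values\n")
  cat("  labels: ", paste(x$label_names, collapse = " / "), "\n")
  invisible(x)
}

#' Default tabular feature set: 9 general features plus 21 ICD indicators
#' @return Named character vector of feature kinds.
#' @export
default_tabular_features <- function() {
  kinds <- c(
    age_at_consult = "numeric", breed = "categorical",
    species = "categorical", gender = "categorical",
    insured = "categorical", neutered = "categorical",
    region = "categorical", practice_id = "categorical",
    premise_id = "categorical"
  )
  icd <- rep("numeric", length(icd_columns()))
  names(icd) <- icd_columns()
  c(kinds, icd)
}

# Fields whose absence makes a record "incomplete" for cohort filtering
# ("missing breed, age, sex, geographical information").
default_required_fields <- function() {
  c("age_at_consult", "breed", "species", "gender", "region")
}
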