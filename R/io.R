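#' Read consultation records from JSONL or CSV
#'
#' Records are returned in file order as a tibble with one row per
#' consultation: identifier columns, the general tabular features, the 21
#' ICD indicator counts as `icd_*` columns, and the free-text `narrative`.
#' In JSONL each line is one record object with a nested `icd_counts` map;
#' in CSV the indicator counts are flattened into `icd_`-prefixed columns.
#' All record invariants are checked and violations reported with row
#' numbers.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @param validate Check record invariants (default `TRUE`).
#' @return A tibble of consultation records.
#' @seealso [write_records()], [validate_records()]
#' @export
read_records <- function(path, format = guess_format(path), validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- match.arg(format, c("jsonl", "csv"))
  recs <- if (format == "jsonl") read_records_jsonl(path) else read_records_csv(path)
  if (validate) validate_records(recs)
  recs
}

guess_format <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
}

empty_records <- function() {
  cols <- record_columns()
  out <- tibble::as_tibble(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  out$animal_id <- character(0)
  out$consult_index <- integer(0)
  out$age_at_consult <- numeric(0)
  for (f in setdiff(general_features(), "age_at_consult")) out[[f]] <- character(0)
  for (f in icd_columns()) out[[f]] <- integer(0)
  out$narrative <- character(0)
  out$practice_id <- character(0)
  out$premise_id <- character(0)
  out
}

read_records_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_records())
  rows <- purrr::imap(lines, function(ln, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(ln, simplifyVector = TRUE),
      error = function(e) stop("parse error at line ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    flatten_record(rec, i)
  })
  dplyr::bind_rows(rows)
}

flatten_record <- function(rec, i) {
  needed <- c("animal_id", "consult_index", general_features(), "narrative")
  missing <- setdiff(needed, names(rec))
  if (length(missing) > 0L) {
    stop("schema error at record ", i, ": missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(rec$icd_counts)) {
    stop("schema error at record ", i, ": missing field(s) icd_counts",
         call. = FALSE)
  }
  icd <- unlist(rec$icd_counts)
  bad <- setdiff(icd_indicator_names(), names(icd))
  if (length(bad) > 0L) {
    stop("schema error at record ", i, ": icd_counts missing indicator(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  row <- tibble::tibble(
    animal_id = as.character(rec$animal_id),
    consult_index = as.integer(rec$consult_index),
    age_at_consult = null_as_na(rec$age_at_consult, as.numeric),
    breed = null_as_na(rec$breed), species = null_as_na(rec$species),
    gender = null_as_na(rec$gender), insured = null_as_na(rec$insured),
    neutered = null_as_na(rec$neutered), region = null_as_na(rec$region),
    practice_id = null_as_na(rec$practice_id),
    premise_id = null_as_na(rec$premise_id),
    narrative = null_as_na(rec$narrative)
  )
  for (nm in icd_indicator_names()) {
    row[[paste0("icd_", nm)]] <- as.integer(icd[[nm]])
  }
  row$narrative <- row$narrative
  row[, record_columns()]
}

null_as_na <- function(x, cast = as.character) {
  if (is.null(x) || length(x) == 0L || (is.character(x) && !nzchar(x))) {
    cast(NA)
  } else {
    cast(x)
  }
}

read_records_csv <- function(path) {
  spec <- readr::cols(
    animal_id = readr::col_character(),
    consult_index = readr::col_integer(),
    age_at_consult = readr::col_double(),
    narrative = readr::col_character(),
    .default = readr::col_character()
  )
  df <- readr::read_csv(path, col_types = spec, progress = FALSE,
                        na = c("", "NA"))
  missing <- setdiff(record_columns(), names(df))
  if (length(missing) > 0L) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cc in icd_columns()) df[[cc]] <- as.integer(df[[cc]])
  df[, record_columns()]
}

#' Validate consultation-record invariants
#'
#' Checks that `consult_index` is unique per animal, ages are non-negative
#' and non-decreasing within an animal, and ICD counts are non-negative
#' integers. Violations raise an error naming the offending rows.
#'
#' @param records A record tibble as returned by [read_records()].
#' @return `records`, invisibly, if valid.
#' @export
validate_records <- function(records) {
  missing <- setdiff(record_columns(), names(records))
  if (length(missing) > 0L) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) return(invisible(records))
  problems <- character(0)

  dup <- records |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$animal_id, .data$consult_index) |>
    dplyr::filter(dplyr::n() > 1L)
  if (nrow(dup) > 0L) {
    problems <- c(problems, paste0(
      "duplicate consult_index within animal at row(s) ",
      paste(dup$.row, collapse = ", ")))
  }

  neg_age <- which(!is.na(records$age_at_consult) & records$age_at_consult < 0)
  if (length(neg_age) > 0L) {
    problems <- c(problems, paste0("negative age_at_consult at row(s) ",
                                   paste(neg_age, collapse = ", ")))
  }

  non_mono <- records |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$animal_id, .data$consult_index) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::filter(!is.na(.data$age_at_consult),
                  .data$age_at_consult <
                    dplyr::lag(.data$age_at_consult,
                               default = -Inf)) |>
    dplyr::ungroup()
  if (nrow(non_mono) > 0L) {
    problems <- c(problems, paste0(
      "age_at_consult decreases within animal at row(s) ",
      paste(non_mono$.row, collapse = ", ")))
  }

  for (cc in icd_columns()) {
    bad <- which(!is.na(records[[cc]]) & records[[cc]] < 0L)
    if (length(bad) > 0L) {
      problems <- c(problems, paste0("negative ", cc, " at row(s) ",
                                     paste(bad, collapse = ", ")))
    }
  }

  if (length(problems) > 0L) {
    stop("invalid records:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(records)
}

#' Write consultation records to JSONL or CSV
#'
#' The inverse of [read_records()]: `read_records(write_records(x, p), p)`
#' reproduces `x` field for field, in order. JSONL nests the indicator
#' counts under an `icd_counts` map; CSV keeps the flat `icd_*` columns.
#' Missing values become JSON `null` / empty CSV cells.
#'
#' @param records Record tibble.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = guess_format(path)) {
  format <- match.arg(format, c("jsonl", "csv"))
  if (format == "csv") {
    readr::write_csv(records[, record_columns()], path, na = "")
    return(invisible(path))
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(records) > 0L) {
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      icd <- as.list(r[, icd_columns()])
      names(icd) <- icd_indicator_names()
      obj <- list(
        animal_id = r$animal_id, consult_index = r$consult_index,
        age_at_consult = r$age_at_consult, breed = r$breed,
        species = r$species, gender = r$gender, insured = r$insured,
        neutered = r$neutered, region = r$region,
        practice_id = r$practice_id, premise_id = r$premise_id,
        icd_counts = icd, narrative = r$narrative
      )
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA), con)
    }
  }
  invisible(path)
}
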