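#' Shoulder-pain diagnosis code table
#'
#' The 29 ICD-10 codes that qualify a primary-care visit as
#' shoulder-pain related, grouped into four clinical categories:
#' subacromial pain (including nonspecific shoulder pain), stiffness
#' (adhesive capsulitis, arthritis), fractures, and dislocations.
#' Range tokens such as `"M751-9"` are expanded over the final digit
#' (M751, M752, ..., M759).
#'
#' @param expand If `TRUE` (default) range tokens are expanded so each row
#'   is one concrete code; if `FALSE` the raw tokens are returned.
#' @return A tibble with columns `category` and `code`.
#' @export
#' @examples
#' diagnosis_code_table()
diagnosis_code_table <- function(expand = TRUE) {
  path <- system.file("extdata", "diagnosis_codes.csv",
                      package = "shouldercoi", mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!expand) {
    return(as_tibble(raw))
  }
  tidyr::unnest(
    mutate(raw, code = purrr::map(.data$code, expand_code_token)),
    "code"
  )
}

# "M751-9" -> M751 ... M759; plain codes pass through normalised
expand_code_token <- function(token) {
  token <- normalize_code(token)
  m <- regmatches(token, regexec("^([A-Z][0-9]+)-([0-9])$", token))[[1]]
  if (length(m) == 0L) {
    return(token)
  }
  stem <- m[2]
  from <- as.integer(substr(stem, nchar(stem), nchar(stem)))
  to <- as.integer(m[3])
  if (to < from) abort(paste0("invalid code range: ", token))
  paste0(substr(stem, 1L, nchar(stem) - 1L), seq(from, to))
}

normalize_code <- function(code) {
  toupper(gsub("[.[:space:]]", "", code))
}

diagnosis_categories <- c("subacromial_pain", "stiffness", "fracture",
                          "dislocation")

#' Classify an ICD-10 code into a shoulder-pain category
#'
#' Matching is exact on the normalised code (dots and whitespace removed,
#' upper-cased). Codes on none of the four lists — including non-shoulder
#' diagnoses recorded at the same visit — return `"not_qualifying"`.
#'
#' @param code Character vector of ICD-10 codes.
#' @param code_table A code table as returned by [diagnosis_code_table()];
#'   override to study alternative code lists.
#' @return Character vector of categories: `"subacromial_pain"`,
#'   `"stiffness"`, `"fracture"`, `"dislocation"` or `"not_qualifying"`.
#' @export
#' @examples
#' classify_diagnosis(c("M751", "S420", "m75.9", "J069"))
classify_diagnosis <- function(code, code_table = diagnosis_code_table()) {
  if (!is.character(code) || any(is.na(code)) || any(!nzchar(code))) {
    abort("diagnosis codes must be non-empty strings")
  }
  idx <- match(normalize_code(code), normalize_code(code_table$code))
  out <- code_table$category[idx]
  out[is.na(out)] <- "not_qualifying"
  out
}

#' Apply the cohort inclusion criteria
#'
#' A patient is included when aged 20-64 (inclusive), resident in one of
#' the study municipalities, and at least one visit during the measurement
#' window carries a qualifying shoulder-pain code.
#'
#' @param patients Tibble with columns `patient_id`, `age`, `municipality`.
#' @param visits Tibble with columns `patient_id`, `date`, `code`.
#' @param window Length-2 `Date` vector (start, end) of the measurement
#'   period.
#' @param age_range Inclusive age bounds, default `c(20, 64)`.
#' @param municipalities Character vector of study municipalities; by
#'   default every municipality present in `patients` qualifies.
#' @param code_table See [classify_diagnosis()].
#' @return `patients` with logical column `included` and character column
#'   `category` (diagnosis category of the first qualifying visit; `NA`
#'   when excluded).
#' @export
include_patients <- function(patients, visits, window,
                             age_range = c(20, 64),
                             municipalities = NULL,
                             code_table = diagnosis_code_table()) {
  window <- as_window(window)
  municipalities <- municipalities %||% unique(patients$municipality)

  qual <- visits |>
    filter(.data$date >= window[1], .data$date <= window[2]) |>
    mutate(category = classify_diagnosis(.data$code, code_table)) |>
    filter(.data$category != "not_qualifying") |>
    arrange(.data$date) |>
    group_by(.data$patient_id) |>
    summarise(category = .data$category[1L], .groups = "drop")

  patients |>
    select(-dplyr::any_of("category")) |>   # recomputed from the visits
    left_join(qual, by = "patient_id") |>
    mutate(
      included = .data$age >= age_range[1] & .data$age <= age_range[2] &
        .data$municipality %in% municipalities & !is.na(.data$category),
      category = ifelse(.data$included, .data$category, NA_character_)
    )
}

as_window <- function(window) {
  window <- as.Date(window)
  if (length(window) != 2L || any(is.na(window)) || window[1] > window[2]) {
    abort("window must be two ordered dates c(start, end)")
  }
  window
}
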