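#' Categorise a treatment duration
#'
#' Durations (days between first and last qualifying visit) are grouped
#' into the four reporting bands: 0-6 weeks, 7-12 weeks, 12-26 weeks and
#' more than 6 months. Half-open day intervals are used so every duration
#' falls in exactly one band: `[0, 42]`, `(42, 84]`, `(84, 182]`,
#' `(182, Inf)`. Week 12 itself (days 78-84) belongs to the 7-12 week
#' band.
#'
#' @param duration_days Non-negative integer vector of episode durations.
#' @return Factor with levels `w0_6`, `w7_12`, `w12_26`, `gt_6m`.
#' @export
#' @examples
#' duration_category(c(0, 42, 43, 100, 183))
duration_category <- function(duration_days) {
  if (!is.numeric(duration_days) || any(duration_days < 0, na.rm = TRUE)) {
    abort("duration_days must be non-negative")
  }
  cut(duration_days, breaks = c(-1, 42, 84, 182, Inf),
      labels = c("w0_6", "w7_12", "w12_26", "gt_6m"))
}

#' Build the primary treatment episode from qualifying visits
#'
#' The treatment episode spans consecutive qualifying visits from the
#' first visit inside the measurement window, chaining forwards and
#' backwards while each inter-visit gap is at most `gap_days` ("at least
#' one visit per month"). A gap whose interval overlaps the holiday window
#' may be up to `2 * gap_days`. The episode's duration is the number of
#' days between its first and last visit.
#'
#' @param dates `Date` vector of qualifying visit dates (any order;
#'   duplicates allowed).
#' @param window Length-2 `Date` vector, the measurement period.
#' @param gap_days Maximum allowed gap between consecutive visits,
#'   default 31.
#' @param holiday_window Length-2 `Date` vector over which the allowed gap
#'   doubles, or `NULL` for no holiday exception. Default July 1 -
#'   August 15 of the window's starting year.
#' @return A one-row tibble: `first_visit`, `last_visit`, `duration_days`,
#'   `duration_category`, `n_visits`, `left_censored`, `right_censored`.
#' @export
#' @examples
#' w <- as.Date(c("2009-01-01", "2009-06-30"))
#' build_episode(as.Date("2009-02-01") + c(0, 28, 56), w)
build_episode <- function(dates, window, gap_days = 31,
                          holiday_window = default_holiday_window(window)) {
  if (length(dates) == 0L || any(is.na(dates))) {
    abort("build_episode() needs at least one qualifying visit date")
  }
  window <- as_window(window)
  dates <- sort(unique(as.Date(dates)))
  in_window <- which(dates >= window[1] & dates <= window[2])
  if (length(in_window) == 0L) {
    abort("no qualifying visit falls inside the measurement window")
  }

  gaps <- diff(as.numeric(dates))
  allowed <- rep(gap_days, length(gaps))
  if (!is.null(holiday_window)) {
    holiday_window <- as_window(holiday_window)
    # a gap is excused when the interval between the two visits overlaps
    # the holiday period
    overlaps <- dates[-length(dates)] <= holiday_window[2] &
      dates[-1] >= holiday_window[1]
    allowed[overlaps] <- 2 * gap_days
  }
  linked <- c(TRUE, gaps <= allowed)  # linked[i]: visit i chains to i - 1
  run <- cumsum(!linked)              # run id per visit
  keep <- run == run[in_window[1L]]   # episode holding first in-window visit

  first_visit <- min(dates[keep])
  last_visit <- max(dates[keep])
  duration <- as.integer(last_visit - first_visit)
  tibble(
    first_visit = first_visit,
    last_visit = last_visit,
    duration_days = duration,
    duration_category = duration_category(duration),
    n_visits = sum(keep),
    left_censored = first_visit < window[1],
    right_censored = last_visit > window[2]
  )
}

default_holiday_window <- function(window) {
  year <- format(as.Date(window[1]), "%Y")
  as.Date(paste0(year, c("-07-01", "-08-15")))
}

#' Build one episode per included patient
#'
#' Applies [build_episode()] to each included patient's qualifying visits
#' and returns one row per patient.
#'
#' @param visits Tibble with `patient_id`, `date`, `code`.
#' @param patients Output of [include_patients()]; only rows with
#'   `included == TRUE` are processed.
#' @inheritParams build_episode
#' @param code_table See [classify_diagnosis()].
#' @return Tibble with `patient_id` plus the [build_episode()] columns.
#' @export
build_episodes <- function(visits, patients, window, gap_days = 31,
                           holiday_window = default_holiday_window(window),
                           code_table = diagnosis_code_table()) {
  ids <- patients$patient_id[patients$included]
  visits |>
    filter(.data$patient_id %in% ids,
           classify_diagnosis(.data$code, code_table) != "not_qualifying") |>
    group_by(.data$patient_id) |>
    reframe(build_episode(.data$date, window, gap_days, holiday_window))
}
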