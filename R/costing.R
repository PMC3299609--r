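#' Sick-leave day equivalents
#'
#' Converts sick-leave prescriptions into countable days. Each
#' prescription contributes its calendar days clipped to the measurement
#' window; overlapping prescriptions for the same patient are merged,
#' taking the highest grade on overlap days. Under `"graded_weighting"`
#' (the default) each day counts as `grade / 100` of a full day, so 10
#' days at grade 50 are 5 full-day equivalents; under `"full_day"` every
#' prescribed day counts in full regardless of grade.
#'
#' @param sickleave Tibble with columns `patient_id`, `start`, `end`,
#'   `grade` (percent in 25/50/75/100).
#' @param window Length-2 `Date` vector; days outside it are not counted.
#' @param grade_policy `"graded_weighting"` or `"full_day"`.
#' @return Tibble with `patient_id`, `sick_leave_days` (calendar days in
#'   window) and `sick_leave_day_equivalents`. Patients without
#'   prescriptions are absent; join against the patient table to recover
#'   zeros.
#' @export
#' @examples
#' w <- as.Date(c("2009-01-01", "2009-06-30"))
#' sl <- tibble::tibble(patient_id = "P1", start = as.Date("2009-02-01"),
#'                      end = as.Date("2009-02-10"), grade = 50)
#' sick_leave_day_equivalents(sl, w)  # 10 days, 5 equivalents
sick_leave_day_equivalents <- function(sickleave, window,
                                       grade_policy = c("graded_weighting",
                                                        "full_day")) {
  grade_policy <- match.arg(grade_policy)
  window <- as_window(window)
  if (nrow(sickleave) == 0L) {
    return(tibble(patient_id = character(), sick_leave_days = numeric(),
                  sick_leave_day_equivalents = numeric()))
  }
  if (any(sickleave$start > sickleave$end)) {
    abort("sick-leave prescriptions must satisfy start <= end")
  }
  if (!all(sickleave$grade %in% c(25, 50, 75, 100))) {
    abort("sick-leave grade must be one of 25, 50, 75, 100")
  }

  clipped <- sickleave |>
    mutate(start = pmax(.data$start, window[1]),
           end = pmin(.data$end, window[2])) |>
    filter(.data$start <= .data$end)
  if (nrow(clipped) == 0L) {
    return(tibble(patient_id = character(), sick_leave_days = numeric(),
                  sick_leave_day_equivalents = numeric()))
  }
  clipped |>
    mutate(day = purrr::map2(.data$start, .data$end, seq, by = "day")) |>
    tidyr::unnest("day") |>
    group_by(.data$patient_id, .data$day) |>
    summarise(grade = max(.data$grade), .groups = "drop") |>
    group_by(.data$patient_id) |>
    summarise(
      sick_leave_days = dplyr::n(),
      sick_leave_day_equivalents = if (grade_policy == "graded_weighting") {
        sum(.data$grade / 100)
      } else {
        as.numeric(dplyr::n())
      },
      .groups = "drop"
    )
}

#' Value sick-leave day equivalents in euros
#'
#' Under the human-capital approach the whole absence is valued at the
#' daily production cost; under the friction-cost method only the fixed
#' friction fraction of that value is counted.
#'
#' @param day_equivalents Numeric vector of full-day equivalents (>= 0).
#' @param schedule A [unit_cost_schedule()]; supplies the euro cost per
#'   full sick-leave day.
#' @param params A [productivity_parameters()]; supplies the valuation
#'   method and friction factor.
#' @return Euro cost vector.
#' @export
#' @examples
#' value_sick_leave(10)                                        # 2050
#' value_sick_leave(10, params = productivity_parameters(
#'   valuation_method = "friction"))                           # 793.35
value_sick_leave <- function(day_equivalents,
                             schedule = unit_cost_schedule(),
                             params = productivity_parameters()) {
  if (any(day_equivalents < 0, na.rm = TRUE)) {
    abort("day_equivalents must be non-negative")
  }
  base <- day_equivalents * schedule$sick_leave_day
  if (params$valuation_method == "friction") {
    base * params$friction_factor
  } else {
    base
  }
}

#' Bottom-up per-patient cost summaries
#'
#' Values each patient's recorded resource use: unit counts times unit
#' costs for GP visits, physiotherapy, x-ray, ultrasound and filled
#' prescriptions (the healthcare components), plus sick leave valued via
#' [sick_leave_day_equivalents()] and [value_sick_leave()]. Every patient
#' in the cohort receives a row; patients without any recorded use get an
#' all-zero summary. Costs are carried at full floating precision; round
#' only when rendering reports.
#'
#' @param cohort An `epr_cohort` (see [generate_cohort()] /
#'   [read_cohort()]), or a list with tibbles `patients`, `visits`,
#'   `sickleave`, `events`.
#' @param schedule A [unit_cost_schedule()].
#' @param params A [productivity_parameters()].
#' @param grade_policy Passed to [sick_leave_day_equivalents()].
#' @param window Measurement period; defaults to the cohort's own window.
#' @return Tibble with one row per patient: `patient_id`, component costs
#'   `gp`, `pt`, `xray`, `ultrasound`, `medicine`, `healthcare_total`,
#'   `sick_leave_days`, `sick_leave_day_equivalents`, `sick_leave`, and
#'   `total = healthcare_total + sick_leave`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20), seed = 7)
#' cost_patients(cohort)
cost_patients <- function(cohort,
                          schedule = unit_cost_schedule(),
                          params = productivity_parameters(),
                          grade_policy = c("graded_weighting", "full_day"),
                          window = cohort$window) {
  grade_policy <- match.arg(grade_policy)
  window <- as_window(window)

  in_win <- function(d) d >= window[1] & d <= window[2]
  visit_counts <- cohort$visits |>
    filter(in_win(.data$date)) |>
    count(.data$patient_id, .data$provider) |>
    tidyr::pivot_wider(names_from = "provider", values_from = "n",
                       values_fill = 0L)
  for (col in c("GP", "PT")) {
    if (!col %in% names(visit_counts)) visit_counts[[col]] <- 0L
  }
  event_counts <- cohort$events |>
    filter(in_win(.data$date)) |>
    count(.data$patient_id, .data$type) |>
    tidyr::pivot_wider(names_from = "type", values_from = "n",
                       values_fill = 0L)
  for (col in c("xray", "ultrasound", "prescription")) {
    if (!col %in% names(event_counts)) event_counts[[col]] <- 0L
  }
  sl <- sick_leave_day_equivalents(cohort$sickleave, window, grade_policy)

  cohort$patients |>
    select("patient_id") |>
    left_join(visit_counts, by = "patient_id") |>
    left_join(event_counts, by = "patient_id") |>
    left_join(sl, by = "patient_id") |>
    mutate(across(-"patient_id", ~ tidyr::replace_na(.x, 0))) |>
    mutate(
      gp = .data$GP * schedule$gp_visit,
      pt = .data$PT * schedule$pt_visit,
      xray = .data$xray * schedule$xray,
      ultrasound = .data$ultrasound * schedule$ultrasound,
      medicine = .data$prescription * schedule$medicine_per_prescription,
      healthcare_total = .data$gp + .data$pt + .data$xray +
        .data$ultrasound + .data$medicine,
      sick_leave = value_sick_leave(.data$sick_leave_day_equivalents,
                                    schedule, params),
      total = .data$healthcare_total + .data$sick_leave
    ) |>
    select("patient_id", "gp", "pt", "xray", "ultrasound", "medicine",
           "healthcare_total", "sick_leave_days",
           "sick_leave_day_equivalents", "sick_leave", "total")
}

#' Estimated secondary-care costs
#'
#' Referrals to an orthopaedic specialist, MRI investigations and
#' ambulatory surgeries generate costs outside primary care, valued at the
#' secondary-care prices of the unit-cost schedule:
#' `n_referrals * orthopaedic_visit + n_mri * mri + n_surgeries *
#' surgery_ambulatory`.
#'
#' @param n_referrals,n_mri,n_surgeries Non-negative counts.
#' @param schedule A [unit_cost_schedule()].
#' @return Euro cost.
#' @export
#' @examples
#' estimate_secondary_costs(29, 10, 4)  # 22475
estimate_secondary_costs <- function(n_referrals, n_mri, n_surgeries,
                                     schedule = unit_cost_schedule()) {
  counts <- c(n_referrals, n_mri, n_surgeries)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers")
  }
  n_referrals * schedule$orthopaedic_visit + n_mri * schedule$mri +
    n_surgeries * schedule$surgery_ambulatory
}
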