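# hand-built cohorts with known resource use, window Jan-Jun 2009

test_window <- function() as.Date(c("2009-01-01", "2009-06-30"))

empty_tbl <- function(which) {
  switch(which,
    patients = tibble::tibble(patient_id = character(), age = numeric(),
                              sex = character(), municipality = character(),
                              referred = logical(), surgery = logical(),
                              postoperative_rehab = logical()),
    visits = tibble::tibble(patient_id = character(),
                            date = as.Date(character()),
                            provider = character(), code = character()),
    sickleave = tibble::tibble(patient_id = character(),
                               start = as.Date(character()),
                               end = as.Date(character()), grade = numeric()),
    events = tibble::tibble(patient_id = character(),
                            date = as.Date(character()), type = character(),
                            detail = character())
  )
}

toy_cohort <- function(patients = NULL, visits = NULL, sickleave = NULL,
                       events = NULL, window = test_window()) {
  structure(
    list(
      patients = patients %||% empty_tbl("patients"),
      visits = visits %||% empty_tbl("visits"),
      sickleave = sickleave %||% empty_tbl("sickleave"),
      events = events %||% empty_tbl("events"),
      window = window, config = NULL
    ),
    class = "epr_cohort"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

toy_patients <- function(ids, age = 40, sex = "female", municipality = "A") {
  tibble::tibble(patient_id = ids, age = age, sex = sex,
                 municipality = municipality, referred = FALSE,
                 surgery = FALSE, postoperative_rehab = FALSE)
}

toy_visits <- function(id, dates, provider = "GP", code = "M751") {
  tibble::tibble(patient_id = id, date = as.Date(dates),
                 provider = provider, code = code)
}

# cohort_margins built from patient-level summaries, for the
# patient-level-vs-margins agreement property
margins_from_summaries <- function(summaries) {
  comps <- c("gp", "pt", "xray", "ultrasound", "medicine",
             "healthcare_total", "sick_leave", "total")
  tbl <- tibble::tibble(
    component = comps,
    mean_units = NA_real_, sd_units = NA_real_, total_units = NA_real_,
    cost_mean = unname(vapply(comps, function(k) mean(summaries[[k]]),
                              numeric(1))),
    cost_sd = unname(vapply(comps, function(k) stats::sd(summaries[[k]]),
                            numeric(1))),
    total_cost = unname(vapply(comps, function(k) sum(summaries[[k]]),
                               numeric(1)))
  )
  structure(tbl, n = nrow(summaries),
            class = c("cohort_margins", class(tbl)))
}
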