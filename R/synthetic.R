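#' Configuration for the synthetic EPR cohort generator
#'
#' Defines the statistical structure of a simulated primary-care
#' shoulder-pain cohort. Defaults emulate the published 204-patient
#' six-month cohort: 103/204 women, ages 20-64 (mean 48, SD 11), the four
#' diagnosis categories in proportions 181/10/7/6, GP visits with mean
#' 0.89 (SD 0.97), physiotherapy visits with mean 3.91 (SD 7.40) and a
#' third of patients with none, per-patient imaging probabilities 57/204
#' (x-ray) and 23/204 (ultrasound), prescription probability 58/204, 20%
#' of patients with any sick leave, heavy-tailed sick-leave durations with
#' overall mean 9.04 days (SD 29.17), and 11% of sick-leave days at a
#' partial grade.
#'
#' Physiotherapy counts use a hurdle model — a point mass at zero plus a
#' shifted negative binomial — the simplest count family that can match a
#' zero share of one third together with an SD far above the mean; GP
#' counts are drawn conditionally on physiotherapy use so that every
#' patient has at least one visit while the marginal moments stay on
#' target. Sick-leave durations use a log-normal with a point mass at
#' zero.
#' Parameters are moment-matched to the configured targets at
#' construction, so miscalibrated targets fail fast with an error naming
#' the offending field.
#'
#' @param n_patients Number of patients (default 204).
#' @param age_range Inclusive age bounds, within 20-64.
#' @param age_mean,age_sd Mean and SD of the (truncated normal) age
#'   distribution.
#' @param female_fraction Probability a patient is female.
#' @param category_weights Named proportions over the four diagnosis
#'   categories; must sum to 1.
#' @param gp_visits_dist `list(mean, sd)` target moments of per-patient GP
#'   visit counts.
#' @param pt_visits_dist `list(mean, sd, zero_prob)` target moments and
#'   zero fraction of physiotherapy visit counts.
#' @param imaging_probs Named per-patient probabilities `c(xray, ultrasound)`.
#' @param rx_prob Probability of one filled prescription.
#' @param sickleave_any_prob Probability of any sick leave during the
#'   window.
#' @param sickleave_days_dist `list(mean, sd)` target moments of overall
#'   (zeros included) sick-leave days.
#' @param sickleave_pt_dependence Strength in `[0, 2]` of the positive
#'   dependence between physiotherapy use and sick-leave incidence (0 =
#'   independent); the marginal incidence stays `sickleave_any_prob`.
#' @param partial_fraction Share of each sick-leave spell's days
#'   prescribed at a partial grade.
#' @param partial_grades Grades (percent of full working time) from which
#'   partial days are drawn uniformly.
#' @param referral_prob,surgery_prob_given_referral,postop_rehab_prob
#'   Probabilities of orthopaedic referral, of surgery among referred
#'   patients, and of attending for postoperative rehabilitation.
#' @param visit_gap_range Integer bounds (days) of the uniform gap between
#'   consecutive visits; the upper bound should not exceed the episode gap
#'   rule (31 days) if single episodes are desired.
#' @param window Length-2 `Date` vector, the measurement period.
#' @param holiday_window Length-2 `Date` vector, the holiday period used
#'   by episode construction (informational for the generator).
#' @param municipalities Municipality labels assigned uniformly.
#' @param seed Default random seed used by [generate_cohort()].
#' @return A list of class `cohort_config` with the calibrated sampling
#'   parameters attached.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 50)
#' cohort <- generate_cohort(cfg, seed = 1)
cohort_config <- function(n_patients = 204,
                          age_range = c(20, 64),
                          age_mean = 48,
                          age_sd = 11,
                          female_fraction = 103 / 204,
                          category_weights = c(subacromial_pain = 181,
                                               stiffness = 10,
                                               fracture = 7,
                                               dislocation = 6) / 204,
                          gp_visits_dist = list(mean = 0.89, sd = 0.97),
                          pt_visits_dist = list(mean = 3.91, sd = 7.40,
                                                zero_prob = 68 / 204),
                          imaging_probs = c(xray = 57 / 204,
                                            ultrasound = 23 / 204),
                          rx_prob = 58 / 204,
                          sickleave_any_prob = 0.20,
                          sickleave_days_dist = list(mean = 9.04, sd = 29.17),
                          sickleave_pt_dependence = 1,
                          partial_fraction = 0.11,
                          partial_grades = c(25, 50, 75),
                          referral_prob = 29 / 204,
                          surgery_prob_given_referral = 4 / 29,
                          postop_rehab_prob = 19 / 204,
                          visit_gap_range = c(3, 28),
                          window = as.Date(c("2009-01-01", "2009-06-30")),
                          holiday_window = NULL,
                          municipalities = c("A", "B"),
                          seed = 1L) {
  check_count(n_patients, "n_patients")
  window <- as_window(window)
  holiday_window <- holiday_window %||% default_holiday_window(window)

  if (length(age_range) != 2L || age_range[1] < 20 || age_range[2] > 64 ||
      age_range[1] > age_range[2]) {
    abort("age_range must be ordered bounds within [20, 64]")
  }
  check_prob(female_fraction, "female_fraction")
  check_prob(rx_prob, "rx_prob")
  check_prob(sickleave_any_prob, "sickleave_any_prob")
  check_prob(partial_fraction, "partial_fraction")
  check_prob(referral_prob, "referral_prob")
  check_prob(surgery_prob_given_referral, "surgery_prob_given_referral")
  check_prob(postop_rehab_prob, "postop_rehab_prob")
  for (p in seq_along(imaging_probs)) {
    check_prob(imaging_probs[p], paste0("imaging_probs[", p, "]"))
  }
  if (!setequal(names(category_weights), diagnosis_categories) ||
      any(category_weights < 0) ||
      abs(sum(category_weights) - 1) > 1e-8) {
    abort("category_weights must be named proportions over the four diagnosis categories summing to 1")
  }
  if (sickleave_pt_dependence < 0 || sickleave_pt_dependence > 2) {
    abort("sickleave_pt_dependence must lie in [0, 2]")
  }
  if (!all(partial_grades %in% c(25, 50, 75))) {
    abort("partial_grades must be drawn from {25, 50, 75}")
  }
  visit_gap_range <- as.integer(visit_gap_range)
  if (length(visit_gap_range) != 2L || visit_gap_range[1] < 1 ||
      visit_gap_range[1] > visit_gap_range[2]) {
    abort("visit_gap_range must be ordered positive integer day bounds")
  }

  # calibrate sampling parameters once, up front
  pt_pars <- hurdle_calibrate(pt_visits_dist$mean, pt_visits_dist$sd,
                            pt_visits_dist$zero_prob, field = "pt_visits_dist")
  gp_pars <- gp_conditional_calibrate(gp_visits_dist$mean, gp_visits_dist$sd,
                                      pt_visits_dist$zero_prob)
  window_days <- as.numeric(window[2] - window[1]) + 1
  sl_pars <- sickleave_calibrate(sickleave_days_dist$mean,
                                 sickleave_days_dist$sd,
                                 sickleave_any_prob, cap = window_days)

  structure(
    list(n_patients = as.integer(n_patients), age_range = age_range,
         age_mean = age_mean, age_sd = age_sd,
         female_fraction = female_fraction,
         category_weights = category_weights[diagnosis_categories],
         gp_visits_dist = gp_visits_dist, pt_visits_dist = pt_visits_dist,
         imaging_probs = imaging_probs, rx_prob = rx_prob,
         sickleave_any_prob = sickleave_any_prob,
         sickleave_days_dist = sickleave_days_dist,
         sickleave_pt_dependence = sickleave_pt_dependence,
         partial_fraction = partial_fraction,
         partial_grades = partial_grades,
         referral_prob = referral_prob,
         surgery_prob_given_referral = surgery_prob_given_referral,
         postop_rehab_prob = postop_rehab_prob,
         visit_gap_range = visit_gap_range,
         window = window, holiday_window = holiday_window,
         municipalities = municipalities, seed = as.integer(seed),
         pt_pars = pt_pars, gp_pars = gp_pars, sl_pars = sl_pars),
    class = "cohort_config"
  )
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0(field, " must be a probability in [0, 1]"))
  }
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    abort(paste0(field, " must be a non-negative integer"))
  }
}

# Moment-match a hurdle count model to (mean, sd, zero_prob): a point mass
# at zero of probability zero_prob and positive counts 1 + NB(mu, size).
# The hurdle decouples the zero share from the overdispersion (a plain or
# zero-inflated negative binomial matched to these moments would force a
# *larger* zero share than observed) and calibrates in closed form:
#   mean_pos = mean / (1 - zero_prob),          mu = mean_pos - 1
#   var_pos  = E[X^2] / (1 - zero_prob) - mean_pos^2
#   size     = mu^2 / (var_pos - mu)            (Inf -> shifted Poisson)
hurdle_calibrate <- function(mean, sd, zero_prob, field = "visits_dist") {
  if (mean <= 0 || sd <= 0 || zero_prob <= 0 || zero_prob >= 1) {
    abort(paste0(field, ": mean and sd must be positive, zero_prob in (0,1)"))
  }
  mean_pos <- mean / (1 - zero_prob)
  mu <- mean_pos - 1
  if (mu <= 0) {
    abort(paste0(field, ": mean too small for the configured zero_prob ",
                 "(positive counts must average above 1)"))
  }
  var_pos <- (sd^2 + mean^2) / (1 - zero_prob) - mean_pos^2
  if (var_pos < 0) {
    abort(paste0(field, ": sd too small for the configured zero_prob"))
  }
  excess <- var_pos - mu
  size <- if (excess > 1e-9) mu^2 / excess else Inf
  list(zero_prob = zero_prob, mu = mu, size = size)
}

rhurdle_nb <- function(n, pars) {
  positive <- rbinom(n, 1L, 1 - pars$zero_prob) == 1L
  x <- integer(n)
  if (any(positive)) {
    k <- sum(positive)
    x[positive] <- 1L + if (is.finite(pars$size)) {
      rnbinom(k, size = pars$size, mu = pars$mu)
    } else {
      stats::rpois(k, pars$mu)
    }
  }
  x
}

# GP counts are sampled conditionally on whether the patient has any PT
# visit: patients with none must have >= 1 GP visit (someone registered the
# diagnosis), modelled as 1 + NB(mu, k); the rest draw NB(mu, k). mu and k
# are chosen so the marginal mean and variance hit the configured targets:
#   mean = p0 + mu,   var = mu + mu^2 / k + p0 (1 - p0)
# where p0 is the configured probability of zero PT visits.
gp_conditional_calibrate <- function(mean, sd, pt_zero_prob) {
  mu <- mean - pt_zero_prob
  if (mu <= 0) {
    abort("gp_visits_dist: mean must exceed pt_visits_dist$zero_prob")
  }
  excess <- sd^2 - mu - pt_zero_prob * (1 - pt_zero_prob)
  size <- if (excess > 1e-9) mu^2 / excess else Inf
  list(mu = mu, size = size)
}

rgp_conditional <- function(pt_zero, pars) {
  n <- length(pt_zero)
  x <- if (is.finite(pars$size)) {
    rnbinom(n, size = pars$size, mu = pars$mu)
  } else {
    stats::rpois(n, pars$mu)
  }
  x + as.integer(pt_zero)
}

# Log-normal duration of a sick-leave spell, calibrated so that the
# *capped* conditional mean E[min(D, cap)] equals mean / any_prob while the
# log-scale variance is set from the uncapped conditional CV.
sickleave_calibrate <- function(mean, sd, any_prob, cap) {
  if (mean <= 0 || sd <= 0) {
    abort("sickleave_days_dist: mean and sd must be positive")
  }
  m_c <- mean / any_prob
  v_c <- sd^2 / any_prob - m_c^2 * (1 - any_prob)
  if (v_c <= 0) {
    abort("sickleave_days_dist: sd too small for the configured any-probability")
  }
  sdlog <- sqrt(log(1 + v_c / m_c^2))
  capped_mean <- function(meanlog) {
    exp(meanlog + sdlog^2 / 2) *
      pnorm((log(cap) - meanlog - sdlog^2) / sdlog) +
      cap * (1 - pnorm((log(cap) - meanlog) / sdlog))
  }
  if (m_c >= cap) {
    abort("sickleave_days_dist: conditional mean exceeds the window length")
  }
  meanlog <- uniroot(function(m) capped_mean(m) - m_c,
                     lower = log(m_c) - sdlog^2 / 2,
                     upper = log(cap) + 5, tol = 1e-10)$root
  list(meanlog = meanlog, sdlog = sdlog, cap = cap)
}

#' Generate a synthetic EPR cohort
#'
#' Draws a cohort of shoulder-pain patients with visit, sick-leave,
#' imaging and prescription records, deterministic for a fixed seed.
#' Patients always have at least one coded visit inside the measurement
#' window (otherwise they would never have entered an EPR extract), all
#' dates fall inside the window, and diagnosis codes are drawn from the
#' code list of the patient's sampled category. Sick-leave incidence is
#' positively associated with physiotherapy use (configurable), producing
#' the heavy upper cost tail in which a fifth of patients carry most of
#' the cohort cost.
#'
#' @param config A [cohort_config()].
#' @param seed Integer random seed; defaults to `config$seed`.
#' @return An object of class `epr_cohort`: a list of tibbles `patients`
#'   (patient_id, age, sex, municipality, referred, surgery,
#'   postoperative_rehab), `visits` (patient_id, date, provider, code),
#'   `sickleave` (patient_id, start, end, grade) and `events` (patient_id,
#'   date, type, detail), plus the `window` and the generating config.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20), seed = 42)
#' cohort$patients
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  window <- config$window
  window_days <- as.numeric(window[2] - window[1]) + 1
  code_table <- diagnosis_code_table()
  codes_by_cat <- split(code_table$code, code_table$category)

  if (n == 0L) {
    return(new_epr_cohort(
      patients = empty_patients(), visits = empty_visits(),
      sickleave = empty_sickleave(), events = empty_events(),
      window = window, config = config
    ))
  }

  id <- sprintf("P%04d", seq_len(n))
  age <- rtrunc_norm(n, config$age_mean, config$age_sd, config$age_range)
  sex <- ifelse(rbinom(n, 1L, config$female_fraction) == 1L,
                "female", "male")
  municipality <- sample(config$municipalities, n, replace = TRUE)
  category <- sample(names(config$category_weights), n, replace = TRUE,
                     prob = config$category_weights)
  referred <- rbinom(n, 1L, config$referral_prob) == 1L
  surgery <- referred & rbinom(n, 1L, config$surgery_prob_given_referral) == 1L
  postop <- rbinom(n, 1L, config$postop_rehab_prob) == 1L

  pt_n <- rhurdle_nb(n, config$pt_pars)
  gp_n <- rgp_conditional(pt_n == 0L, config$gp_pars)

  visits <- purrr::map(seq_len(n), function(i) {
    total <- gp_n[i] + pt_n[i]
    gaps <- if (total > 1L) {
      sample(seq(config$visit_gap_range[1], config$visit_gap_range[2]),
             total - 1L, replace = TRUE)
    } else {
      integer(0)
    }
    span <- sum(gaps)
    if (span > window_days - 1) {           # compress to fit the window
      gaps <- floor(gaps * (window_days - 1) / span)
      span <- sum(gaps)
    }
    start <- sample.int(window_days - span, 1L) - 1L
    tibble(
      patient_id = id[i],
      date = window[1] + start + cumsum(c(0L, gaps)),
      provider = sample(c(rep("GP", gp_n[i]), rep("PT", pt_n[i]))),
      code = sample(codes_by_cat[[category[i]]], total, replace = TRUE)
    )
  }) |>
    purrr::list_rbind()

  # sick-leave incidence tilted towards heavy physiotherapy users while
  # keeping the marginal probability at sickleave_any_prob
  tilt <- 1 + config$sickleave_pt_dependence *
    ((rank(pt_n, ties.method = "average") - 0.5) / n - 0.5)
  p_any <- pmin(1, pmax(0, config$sickleave_any_prob * tilt / mean(tilt)))
  any_sl <- rbinom(n, 1L, p_any) == 1L

  sickleave <- purrr::map(which(any_sl), function(i) {
    days <- min(round(rlnorm(1, config$sl_pars$meanlog,
                             config$sl_pars$sdlog)),
                config$sl_pars$cap)
    days <- max(days, 1)
    start <- window[1] + sample.int(window_days - days + 1L, 1L) - 1L
    partial_days <- round(config$partial_fraction * days)
    if (partial_days >= 1 && partial_days < days) {
      full_days <- days - partial_days
      starts <- c(start, start + full_days)
      ends <- c(start + full_days - 1, start + days - 1)
      tibble(
        patient_id = id[i],
        start = starts,
        end = ends,
        grade = c(100, sample(config$partial_grades, 1L))
      )
    } else {
      tibble(patient_id = id[i], start = start, end = start + days - 1,
             grade = 100)
    }
  }) |>
    purrr::list_rbind()
  if (nrow(sickleave) == 0L) sickleave <- empty_sickleave()

  event_date <- function(idx) {
    as.Date(vapply(idx, function(i) {
      d <- visits$date[visits$patient_id == id[i]]
      as.numeric(d[sample.int(length(d), 1L)])
    }, numeric(1)), origin = "1970-01-01")
  }
  xray_i <- which(rbinom(n, 1L, config$imaging_probs[["xray"]]) == 1L)
  us_i <- which(rbinom(n, 1L, config$imaging_probs[["ultrasound"]]) == 1L)
  rx_i <- which(rbinom(n, 1L, config$rx_prob) == 1L)
  events <- bind_rows(
    tibble(patient_id = id[xray_i], date = event_date(xray_i),
           type = "xray", detail = NA_character_),
    tibble(patient_id = id[us_i], date = event_date(us_i),
           type = "ultrasound", detail = NA_character_),
    tibble(patient_id = id[rx_i], date = event_date(rx_i),
           type = "prescription",
           detail = sample(c("analgesic", "NSAID"), length(rx_i),
                           replace = TRUE))
  )
  if (nrow(events) == 0L) events <- empty_events()

  new_epr_cohort(
    patients = tibble(patient_id = id, age = age, sex = sex,
                      municipality = municipality, category = category,
                      referred = referred, surgery = surgery,
                      postoperative_rehab = postop),
    visits = arrange(visits, .data$patient_id, .data$date),
    sickleave = arrange(sickleave, .data$patient_id, .data$start),
    events = arrange(events, .data$patient_id, .data$date),
    window = window, config = config
  )
}

rtrunc_norm <- function(n, mean, sd, range) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2])) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  round(x)
}

new_epr_cohort <- function(patients, visits, sickleave, events, window,
                           config) {
  structure(list(patients = patients, visits = visits,
                 sickleave = sickleave, events = events,
                 window = window, config = config),
            class = "epr_cohort")
}

empty_patients <- function() {
  tibble(patient_id = character(), age = numeric(), sex = character(),
         municipality = character(), category = character(),
         referred = logical(), surgery = logical(),
         postoperative_rehab = logical())
}
empty_visits <- function() {
  tibble(patient_id = character(), date = as.Date(character()),
         provider = character(), code = character())
}
empty_sickleave <- function() {
  tibble(patient_id = character(), start = as.Date(character()),
         end = as.Date(character()), grade = numeric())
}
empty_events <- function() {
  tibble(patient_id = character(), date = as.Date(character()),
         type = character(), detail = character())
}

#' @export
print.epr_cohort <- function(x, ...) {
  cat("Synthetic EPR cohort: ", nrow(x$patients), " patients, ",
      nrow(x$visits), " visits, ", nrow(x$sickleave),
      " sick-leave prescriptions, ", nrow(x$events), " events\n",
      "window: ", format(x$window[1]), " to ", format(x$window[2]), "\n",
      sep = "")
  invisible(x)
}
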