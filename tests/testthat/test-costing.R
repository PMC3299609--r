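w <- test_window()

test_that("daily productivity cost grosses income up by the loadings", {
  expect_equal(daily_productivity_cost(100), 168)
  expect_equal(daily_productivity_cost(0), 0)
  # inverse of the default 205/day at the default loadings
  expect_equal(daily_productivity_cost(205 / 1.68), 205, tolerance = 0.1 / 205)
  expect_error(daily_productivity_cost(-1), "non-negative")
})

test_that("sick-leave day equivalents respect grade policy and window", {
  sl <- tibble::tibble(patient_id = "A", start = as.Date("2009-02-01"),
                       end = as.Date("2009-02-10"), grade = 100)
  expect_equal(sick_leave_day_equivalents(sl, w)$sick_leave_day_equivalents,
               10)
  sl$grade <- 50
  expect_equal(sick_leave_day_equivalents(sl, w)$sick_leave_day_equivalents,
               5)
  expect_equal(
    sick_leave_day_equivalents(sl, w,
                               "full_day")$sick_leave_day_equivalents,
    10)
  two <- tibble::tibble(
    patient_id = "A",
    start = as.Date(c("2009-02-01", "2009-02-11")),
    end = as.Date(c("2009-02-10", "2009-02-20")),
    grade = c(100, 50)
  )
  expect_equal(
    sick_leave_day_equivalents(two, w,
                               "full_day")$sick_leave_day_equivalents,
    20)
  expect_equal(sick_leave_day_equivalents(two, w)$sick_leave_day_equivalents,
               15)
})

test_that("overlapping prescriptions merge at the maximum grade", {
  overlap <- tibble::tibble(
    patient_id = "A",
    start = as.Date(c("2009-02-01", "2009-02-06")),
    end = as.Date(c("2009-02-10", "2009-02-15")),
    grade = c(50, 100)
  )
  out <- sick_leave_day_equivalents(overlap, w)
  expect_equal(out$sick_leave_days, 15)           # union of days
  expect_equal(out$sick_leave_day_equivalents, 5 * 0.5 + 10 * 1)
})

test_that("prescriptions are clipped to the measurement window", {
  sl <- tibble::tibble(patient_id = "A", start = as.Date("2008-12-25"),
                       end = as.Date("2009-01-05"), grade = 100)
  expect_equal(sick_leave_day_equivalents(sl, w)$sick_leave_days, 5)
  outside <- tibble::tibble(patient_id = "A", start = as.Date("2008-01-01"),
                            end = as.Date("2008-01-10"), grade = 100)
  expect_equal(nrow(sick_leave_day_equivalents(outside, w)), 0)
})

test_that("sick leave is valued per method", {
  expect_equal(value_sick_leave(10), 2050)
  fr <- productivity_parameters(valuation_method = "friction")
  expect_equal(value_sick_leave(10, params = fr), 793.35)
  expect_equal(value_sick_leave(0, params = fr), 0)
})

test_that("bottom-up per-patient costs follow the unit-cost schedule", {
  cohort <- toy_cohort(
    patients = toy_patients(c("A", "B", "C")),
    visits = dplyr::bind_rows(
      toy_visits("A", "2009-02-01", "GP"),
      toy_visits("A", c("2009-02-10", "2009-02-20"), "PT"),
      toy_visits("B", "2009-03-01", "GP")
    ),
    events = tibble::tibble(
      patient_id = c("B", "B"),
      date = as.Date("2009-03-01"),
      type = c("xray", "ultrasound"), detail = NA_character_
    )
  )
  cs <- cost_patients(cohort)
  a <- cs[cs$patient_id == "A", ]
  expect_equal(a$healthcare_total, 107 + 2 * 50)
  expect_equal(a$total, 207)
  b <- cs[cs$patient_id == "B", ]
  expect_equal(b$xray + b$ultrasound, 65 + 124)
  c_row <- cs[cs$patient_id == "C", ]                 # no utilization at all
  expect_equal(c_row$total, 0)
  expect_equal(c_row$healthcare_total, 0)
  # type invariants
  expect_equal(cs$healthcare_total,
               cs$gp + cs$pt + cs$xray + cs$ultrasound + cs$medicine)
  expect_equal(cs$total, cs$healthcare_total + cs$sick_leave)
})

test_that("costs are linear in each unit cost", {
  cohort <- generate_cohort(cohort_config(n_patients = 60), seed = 8)
  base <- cost_patients(cohort)
  for (comp in c("gp_visit", "pt_visit", "xray", "ultrasound",
                 "medicine_per_prescription", "sick_leave_day")) {
    args <- list(); args[[comp]] <- 2 * unit_cost_schedule()[[comp]]
    doubled <- cost_patients(cohort, do.call(unit_cost_schedule, args))
    col <- c(gp_visit = "gp", pt_visit = "pt", xray = "xray",
             ultrasound = "ultrasound",
             medicine_per_prescription = "medicine",
             sick_leave_day = "sick_leave")[[comp]]
    expect_equal(doubled[[col]], 2 * base[[col]])
    untouched <- setdiff(c("gp", "pt", "xray", "ultrasound", "medicine",
                           "sick_leave"), col)
    for (other in untouched) expect_equal(doubled[[other]], base[[other]])
  }
})

test_that("friction-valued totals never exceed human-capital totals", {
  cohort <- generate_cohort(cohort_config(n_patients = 120), seed = 9)
  hc <- cost_patients(cohort)
  fr <- cost_patients(cohort, params = productivity_parameters(
    valuation_method = "friction"))
  expect_true(all(fr$total <= hc$total + 1e-12))
  has_sl <- hc$sick_leave > 0
  expect_true(all(fr$total[has_sl] < hc$total[has_sl]))
  expect_equal(fr$total[!has_sl], hc$total[!has_sl])
})

test_that("cohort totals are additive over patients", {
  cohort <- generate_cohort(cohort_config(n_patients = 50), seed = 10)
  cs <- cost_patients(cohort)
  shuffled <- cs[sample(nrow(cs)), ]
  expect_equal(sum(shuffled$total), sum(cs$total))
  chunks <- split(cs, rep(1:3, length.out = nrow(cs)))
  expect_equal(sum(vapply(chunks, function(d) sum(d$total), numeric(1))),
               sum(cs$total))
})

test_that("secondary-care estimate prices referrals, MRI and surgery", {
  expect_equal(estimate_secondary_costs(29, 10, 4), 22475)
  expect_equal(estimate_secondary_costs(0, 0, 0), 0)
  expect_equal(estimate_secondary_costs(1, 1, 1), 335 + 308 + 2420)
  expect_error(estimate_secondary_costs(-1, 0, 0), "non-negative")
})

test_that("annualization doubles six-month costs", {
  expect_equal(annualize(2069.4), 4138.8)
  expect_equal(annualize(0), 0)
  expect_equal(annualize(326.22), 652.44)
  expect_error(annualize(-1), "non-negative")
})
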