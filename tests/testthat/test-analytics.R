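test_that("sample statistics are computed per component", {
  s <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    gp = c(100, 200, 300), pt = 0, xray = 0, ultrasound = 0, medicine = 0,
    healthcare_total = c(100, 200, 300),
    sick_leave_days = 0, sick_leave_day_equivalents = 0, sick_leave = 0,
    total = c(100, 200, 300)
  )
  r <- summarize_cohort(s)
  tot <- r[r$component == "total", ]
  expect_equal(tot$mean, 200)
  expect_equal(tot$median, 200)
  expect_equal(tot$sd, 100)
  expect_equal(tot$total, 600)
})

test_that("z-normal confidence intervals reproduce the printed intervals", {
  r <- summarize_cohort(load_published_margins())
  half_up <- function(x) floor(x + 0.5)
  tot <- r[r$component == "total", ]
  expect_equal(half_up(c(tot$ci_low, tot$ci_high)), c(1283, 2856))
  hc <- r[r$component == "healthcare_total", ]
  expect_equal(half_up(c(hc$ci_low, hc$ci_high)), c(273, 380))
  # the CI half-width itself: 1.96 x 5730 / sqrt(204)
  expect_equal(tot$ci_high - tot$mean, qnorm(0.975) * 5730 / sqrt(204))
})

test_that("component means sum to the total mean and shares sum to one", {
  cs <- cost_patients(generate_cohort(cohort_config(n_patients = 80),
                                      seed = 4))
  r <- summarize_cohort(cs)
  comps <- c("gp", "pt", "xray", "ultrasound", "medicine", "sick_leave")
  expect_equal(sum(r$mean[r$component %in% comps]),
               r$mean[r$component == "total"])
  expect_equal(sum(r$share_total[r$component %in% comps]), 1,
               tolerance = 1e-9)
  expect_equal(sum(r$share_healthcare[r$component %in%
                                        setdiff(comps, "sick_leave")]), 1,
               tolerance = 1e-9)
})

test_that("patient-level and margins-derived reports agree", {
  cs <- cost_patients(generate_cohort(cohort_config(n_patients = 60),
                                      seed = 14))
  from_patients <- summarize_cohort(cs)
  from_margins <- summarize_cohort(margins_from_summaries(cs))
  for (col in c("mean", "sd", "total", "ci_low", "ci_high")) {
    expect_equal(from_margins[[col]], from_patients[[col]],
                 tolerance = 1e-12)
  }
})

test_that("confidence intervals are undefined below n = 2", {
  one <- tibble::tibble(patient_id = "A", gp = 107, pt = 0, xray = 0,
                        ultrasound = 0, medicine = 0,
                        healthcare_total = 107, sick_leave_days = 0,
                        sick_leave_day_equivalents = 0, sick_leave = 0,
                        total = 107)
  r <- summarize_cohort(one)
  expect_true(all(is.na(r$ci_low)))
  expect_equal(r$mean[r$component == "total"], 107)
})

test_that("concentration share behaves at the boundaries", {
  expect_equal(concentration_share(c(5, 5, 5), 1), 1)
  expect_equal(concentration_share(rep(10, 10), 0.2), 0.2)
  expect_equal(concentration_share(c(1000, rep(0, 9)), 0.1), 1)
  expect_error(concentration_share(rep(0, 5), 0.2), "undefined")
  expect_error(concentration_share(c(1, 2), 0), "top_fraction")
})

test_that("concentration share is monotone in the top fraction", {
  withr::with_seed(21, {
    totals <- rlnorm(100, 5, 1.5)
    fr <- seq(0.05, 1, by = 0.05)
    shares <- vapply(fr, concentration_share, numeric(1), totals = totals)
    expect_true(all(diff(shares) >= -1e-12))
    expect_equal(shares[length(shares)], 1)
  })
})

test_that("subgroup report matches the published shares from margins", {
  sg <- subgroup_report(load_published_margins("full"),
                        subgroup_margins = load_published_margins("highcost"))
  expect_equal(round(100 * sg$share_total), 91)
  expect_equal(round(100 * sg$share_healthcare), 44)
  expect_equal(sg$n_subgroup, 45L)
})

test_that("subgroup report agrees with concentration arithmetic", {
  cs <- cost_patients(generate_cohort(cohort_config(n_patients = 100),
                                      seed = 15))
  sorted <- sort(cs$total, decreasing = TRUE)
  k <- 20
  thr <- (sorted[k] + sorted[k + 1]) / 2          # cut between ranks k, k+1
  sg <- subgroup_report(cs, threshold = thr)
  expect_equal(sg$n_subgroup, k)
  expect_equal(sg$share_total, concentration_share(cs$total, k / 100))
  empty <- subgroup_report(cs, threshold = max(cs$total) + 1)
  expect_equal(empty$n_subgroup, 0)
  expect_equal(empty$share_total, 0)
})

test_that("a known multiplicative gender effect is recovered", {
  withr::with_seed(31, {
    n <- 2000
    df <- tibble::tibble(
      municipality = sample(c("A", "B"), n, TRUE),
      sex = sample(c("female", "male"), n, TRUE),
      age = runif(n, 20, 64),
      total = rlnorm(n, 5 + 0.5 * (sex == "male"), 1),
      healthcare_total = total
    )
    fit <- fit_log_cost_regression(df, "total")
    est <- broom::tidy(fit)
    gender <- est$estimate[grepl("gender", est$term)]
    expect_lt(abs(gender - 0.5), 0.15)
    expect_equal(glance(fit)$n_observations, n)
  })
})

test_that("null covariate effects stay within two standard errors", {
  withr::with_seed(32, {
    reps <- 100
    ok <- vapply(seq_len(reps), function(i) {
      n <- 204
      df <- tibble::tibble(
        municipality = sample(c("A", "B"), n, TRUE),
        sex = sample(c("female", "male"), n, TRUE),
        age = runif(n, 20, 64),
        total = rlnorm(n, 5, 1),
        healthcare_total = total
      )
      est <- broom::tidy(fit_log_cost_regression(df, "total"))
      est <- est[est$term != "(Intercept)", ]
      abs(est$estimate) < 2 * est$std.error
    }, logical(3))
    # ~95% coverage per coefficient expected under the null
    expect_true(all(rowMeans(ok) >= 0.90))
  })
})

test_that("degenerate designs are rejected with the covariate named", {
  df <- tibble::tibble(
    municipality = "A", sex = rep(c("female", "male"), 10),
    age = runif(20, 20, 64), total = rlnorm(20, 5, 1),
    healthcare_total = total
  )
  expect_error(fit_log_cost_regression(df, "total"), "municipality")
  few <- df[1:5, ]
  expect_error(fit_log_cost_regression(few, "total"), "at least 10")
})

test_that("zero-cost patients are excluded from the log fit and counted", {
  withr::with_seed(33, {
    n <- 50
    df <- tibble::tibble(
      municipality = sample(c("A", "B"), n, TRUE),
      sex = sample(c("female", "male"), n, TRUE),
      age = runif(n, 20, 64),
      total = c(rep(0, 5), rlnorm(n - 5, 5, 1)),
      healthcare_total = total
    )
    fit <- fit_log_cost_regression(df, "total")
    expect_equal(fit$n_excluded, 5)
    expect_equal(fit$n_observations, n - 5)
  })
})
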