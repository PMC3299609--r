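margins <- load_published_margins()

test_that("scenario validation catches malformed inputs", {
  expect_error(sensitivity_scenario("x", c(spa_visit = 0.3)), "unknown")
  expect_error(sensitivity_scenario("x", c(gp = -1)), "exceed -1")
  expect_error(sensitivity_scenario("", c(gp = 0.3)), "non-empty")
  expect_error(sensitivity_scenario("x", method = "bootstrap"), "friction")
  expect_error(
    scenario_table(margins, list(sensitivity_scenario("a", c(gp = 0.1)),
                                 sensitivity_scenario("a", c(gp = 0.2)))),
    "duplicate"
  )
})

test_that("the identity scenario is a fixed point", {
  id <- sensitivity_scenario("identity")
  for (base in list(margins,
                    cost_patients(generate_cohort(
                      cohort_config(n_patients = 50), seed = 16)))) {
    res <- run_scenario(base, id)
    expect_equal(res$pct_change_total, 0)
    expect_equal(res$pct_change_healthcare, 0)
    base_row <- run_scenario(base, sensitivity_scenario("base"))
    expect_equal(res[-1], base_row[-1])
  }
})

test_that("one-way changes equal the closed-form linear oracle exactly", {
  cs <- cost_patients(generate_cohort(cohort_config(n_patients = 80),
                                      seed = 17))
  comps <- c("gp", "pt", "xray", "ultrasound", "medicine", "sick_leave")
  for (base in list(margins, cs)) {
    base_totals <- if (inherits(base, "cohort_margins")) {
      stats::setNames(base$total_cost[match(comps, base$component)], comps)
    } else {
      vapply(comps, function(k) sum(base[[k]]), numeric(1))
    }
    grand <- sum(base_totals)
    hc <- sum(base_totals[setdiff(comps, "sick_leave")])
    for (comp in comps) {
      for (delta in c(-0.5, 0.3, 1)) {
        sc <- sensitivity_scenario("s", stats::setNames(delta, comp))
        res <- run_scenario(base, sc)
        expect_equal(res$pct_change_total,
                     delta * base_totals[[comp]] / grand * 100,
                     tolerance = 1e-12)
        expected_hc <- if (comp == "sick_leave") {
          0
        } else {
          delta * base_totals[[comp]] / hc * 100
        }
        expect_equal(res$pct_change_healthcare, expected_hc,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("multi-way changes superpose the one-way changes", {
  multi <- sensitivity_scenario("multi", c(pt = 0.3, gp = 0.5, xray = -0.2))
  res <- run_scenario(margins, multi)
  ones <- lapply(c(pt = 0.3, gp = 0.5, xray = -0.2) |> seq_along(),
                 function(i) {
                   m <- c(pt = 0.3, gp = 0.5, xray = -0.2)[i]
                   run_scenario(margins, sensitivity_scenario("o", m))
                 })
  expect_equal(res$pct_change_total,
               sum(vapply(ones, function(r) r$pct_change_total, numeric(1))),
               tolerance = 1e-12)
  expect_equal(res$pct_change_healthcare,
               sum(vapply(ones, function(r) r$pct_change_healthcare,
                          numeric(1))),
               tolerance = 1e-12)
})

test_that("healthcare and sick-leave perturbations do not cross-talk", {
  sl <- run_scenario(margins, sensitivity_scenario("sl",
                                                   c(sick_leave = 0.3)))
  expect_equal(sl$pct_change_healthcare, 0)
  hc <- run_scenario(margins, sensitivity_scenario("hc", c(pt = 0.3,
                                                           gp = 0.5)))
  expect_equal(hc$pct_change_sick_leave, 0)
})

test_that("the friction switch scales only the sick-leave component", {
  res <- run_method_switch(margins)
  expect_equal(res$pct_change_healthcare, 0)
  expect_equal(res$pct_change_sick_leave, -61.3, tolerance = 1e-3)
  expect_equal(res$total_mean, 1001, tolerance = 1e-3)
  unit <- run_method_switch(margins,
                            productivity_parameters(friction_factor = 1))
  expect_equal(unit$pct_change_total, 0)
})

test_that("scenario order does not affect per-scenario results", {
  scens <- default_scenarios()
  fwd <- scenario_table(margins, scens)
  rev_ <- scenario_table(margins, rev(scens))
  expect_equal(dplyr::arrange(fwd, scenario),
               dplyr::arrange(rev_, scenario))
  expect_equal(fwd$scenario[1], "Base case scenario")
  expect_equal(nrow(fwd), length(scens) + 1)
})

test_that("patient-level scenarios recompute perturbed intervals", {
  cs <- cost_patients(generate_cohort(cohort_config(n_patients = 80),
                                      seed = 18))
  res <- run_scenario(cs, sensitivity_scenario("sl", c(sick_leave = 0.3)))
  new_total <- cs$healthcare_total + 1.3 * cs$sick_leave
  expect_equal(res$total_mean, mean(new_total))
  expect_equal(res$total_ci_high,
               mean(new_total) + qnorm(0.975) * sd(new_total) /
                 sqrt(length(new_total)))
  # margins cannot supply a perturbed-total interval
  m_res <- run_scenario(margins, sensitivity_scenario("sl",
                                                      c(sick_leave = 0.3)))
  expect_true(is.na(m_res$total_ci_low))
  expect_false(is.na(m_res$healthcare_ci_low))  # untouched aggregate keeps CI
})
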