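#' Define a sensitivity scenario
#'
#' A deterministic scenario perturbs one or more unit costs by a relative
#' multiplier (e.g. `+0.30` for +30%) and/or switches the productivity
#' valuation to the friction-cost method. Utilization frequencies are
#' never changed — only prices — so the cost model responds linearly.
#'
#' @param name Unique scenario label.
#' @param multipliers Named numeric vector of relative changes, names from
#'   `gp`, `pt`, `xray`, `ultrasound`, `medicine`, `sick_leave` (the
#'   sick-leave entry perturbs the price per sick-leave day). All values
#'   must exceed -1 (prices cannot go negative).
#' @param method Optional valuation override, currently `"friction"`.
#' @return A list of class `sensitivity_scenario`.
#' @export
#' @examples
#' sensitivity_scenario("sick leave +30%", c(sick_leave = 0.30))
#' sensitivity_scenario("friction method", method = "friction")
sensitivity_scenario <- function(name, multipliers = numeric(),
                                 method = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("scenario name must be a non-empty string")
  }
  if (length(multipliers)) {
    unknown <- setdiff(names(multipliers), cost_components())
    if (length(unknown) || is.null(names(multipliers))) {
      abort(paste0("unknown component(s) in multipliers: ",
                   paste(unknown, collapse = ", "),
                   "; allowed: ", paste(cost_components(), collapse = ", ")))
    }
    if (any(multipliers <= -1)) {
      abort("multipliers must exceed -1 (prices cannot be negative)")
    }
  }
  if (!is.null(method) && !identical(method, "friction")) {
    abort('method override must be NULL or "friction"')
  }
  structure(list(name = name, multipliers = multipliers, method = method),
            class = "sensitivity_scenario")
}

#' The published sensitivity-analysis scenario set
#'
#' The one-way scenarios (physiotherapy +/-30%, GP +/-50%, sick-leave day
#' +/-30%, x-ray +/-30%, ultrasound +/-30%, medicine +100%/-50%), two
#' multi-way combinations, and the friction-cost method switch.
#'
#' The printed label of the larger multi-way scenario names PT, GP, x-ray
#' and ultrasound, but the published means for that row (total 2186,
#' healthcare 443) are only reproduced when the medicine price also moves
#' by +/-30%; the default set therefore includes medicine in that
#' scenario.
#'
#' @return List of [sensitivity_scenario()] objects.
#' @export
default_scenarios <- function() {
  list(
    sensitivity_scenario("PT cost per consultation +30%", c(pt = 0.30)),
    sensitivity_scenario("PT cost per consultation -30%", c(pt = -0.30)),
    sensitivity_scenario("GP cost per consultation +50%", c(gp = 0.50)),
    sensitivity_scenario("GP cost per consultation -50%", c(gp = -0.50)),
    sensitivity_scenario("Sick leave cost per day +30%",
                         c(sick_leave = 0.30)),
    sensitivity_scenario("Sick leave cost per day -30%",
                         c(sick_leave = -0.30)),
    sensitivity_scenario("X-ray cost per consultation +30%",
                         c(xray = 0.30)),
    sensitivity_scenario("X-ray cost per consultation -30%",
                         c(xray = -0.30)),
    sensitivity_scenario("Ultrasound cost per consultation +30%",
                         c(ultrasound = 0.30)),
    sensitivity_scenario("Ultrasound cost per consultation -30%",
                         c(ultrasound = -0.30)),
    sensitivity_scenario("Medicine, unit used +100%", c(medicine = 1.00)),
    sensitivity_scenario("Medicine, unit used -50%", c(medicine = -0.50)),
    sensitivity_scenario("PT +30%, GP +50%", c(pt = 0.30, gp = 0.50)),
    sensitivity_scenario("PT -30%, GP -50%", c(pt = -0.30, gp = -0.50)),
    sensitivity_scenario("PT, x-ray, ultrasound, medicine +30%, GP +50%",
                         c(pt = 0.30, gp = 0.50, xray = 0.30,
                           ultrasound = 0.30, medicine = 0.30)),
    sensitivity_scenario("PT, x-ray, ultrasound, medicine -30%, GP -50%",
                         c(pt = -0.30, gp = -0.50, xray = -0.30,
                           ultrasound = -0.30, medicine = -0.30)),
    sensitivity_scenario("Sick leave cost based on friction method",
                         method = "friction")
  )
}

#' Run one sensitivity scenario
#'
#' Recomputes the cohort cost summary with each perturbed component's cost
#' scaled by `1 + multiplier` for every patient (frequencies unchanged); a
#' friction-method override multiplies the sick-leave component by the
#' friction factor. From patient-level summaries the perturbed 95%
#' confidence intervals are recomputed from the perturbed per-patient
#' distribution; from printed margins a CI is carried over only for an
#' aggregate the scenario leaves untouched (component covariances are not
#' recoverable from margins).
#'
#' @param base Patient cost summaries (tibble from [cost_patients()]) or a
#'   `cohort_margins` object.
#' @param scenario A [sensitivity_scenario()].
#' @param params A [productivity_parameters()] supplying the friction
#'   factor.
#' @param ... Unused.
#' @return A one-row tibble: `scenario`, `pct_change_total`,
#'   `pct_change_healthcare`, `pct_change_sick_leave`, `total_mean`,
#'   `total_ci_low`, `total_ci_high`, `healthcare_mean`,
#'   `healthcare_ci_low`, `healthcare_ci_high`.
#' @export
#' @examples
#' run_scenario(load_published_margins(),
#'              sensitivity_scenario("sick leave +30%",
#'                                   c(sick_leave = 0.30)))
run_scenario <- function(base, scenario,
                         params = productivity_parameters(), ...) {
  UseMethod("run_scenario")
}

scenario_factors <- function(scenario, params) {
  stopifnot(inherits(scenario, "sensitivity_scenario"))
  f <- setNames(rep(1, length(cost_components())), cost_components())
  f[names(scenario$multipliers)] <- 1 + scenario$multipliers
  if (identical(scenario$method, "friction")) {
    f["sick_leave"] <- f["sick_leave"] * params$friction_factor
  }
  f
}

#' @export
run_scenario.data.frame <- function(base, scenario,
                                    params = productivity_parameters(),
                                    ...) {
  f <- scenario_factors(scenario, params)
  new <- base
  for (comp in cost_components()) {
    new[[comp]] <- base[[comp]] * f[[comp]]
  }
  new$healthcare_total <- rowSums(new[healthcare_components()])
  new$total <- new$healthcare_total + new$sick_leave

  n <- nrow(base)
  z <- qnorm(0.975)
  ci <- function(v) {
    if (n >= 2) mean(v) + c(-1, 1) * z * sd(v) / sqrt(n) else c(NA_real_,
                                                                NA_real_)
  }
  tci <- ci(new$total)
  hci <- ci(new$healthcare_total)
  scenario_result(
    scenario$name,
    base_total = mean(base$total), base_hc = mean(base$healthcare_total),
    base_sl = mean(base$sick_leave),
    new_total = mean(new$total), new_hc = mean(new$healthcare_total),
    new_sl = mean(new$sick_leave),
    total_ci = tci, hc_ci = hci
  )
}

#' @export
run_scenario.cohort_margins <- function(base, scenario,
                                        params = productivity_parameters(),
                                        ...) {
  f <- scenario_factors(scenario, params)
  n <- attr(base, "n")
  comp_totals <- setNames(margin_total(base, cost_components()),
                          cost_components())
  new_totals <- comp_totals * f[cost_components()]
  base_hc <- sum(comp_totals[healthcare_components()])
  new_hc <- sum(new_totals[healthcare_components()])
  base_total <- base_hc + comp_totals[["sick_leave"]]
  new_total <- new_hc + new_totals[["sick_leave"]]

  z <- qnorm(0.975)
  base_ci <- function(component) {
    m <- margin_total(base, component) / n
    s <- base$cost_sd[match(component, base$component)]
    m + c(-1, 1) * z * s / sqrt(n)
  }
  # perturbed CIs need component covariances; only an untouched aggregate
  # keeps its printed interval
  hc_untouched <- all(f[healthcare_components()] == 1)
  all_untouched <- hc_untouched && f[["sick_leave"]] == 1
  tci <- if (all_untouched) base_ci("total") else c(NA_real_, NA_real_)
  hci <- if (hc_untouched) base_ci("healthcare_total") else c(NA_real_,
                                                              NA_real_)
  scenario_result(
    scenario$name,
    base_total = base_total / n, base_hc = base_hc / n,
    base_sl = comp_totals[["sick_leave"]] / n,
    new_total = new_total / n, new_hc = new_hc / n,
    new_sl = new_totals[["sick_leave"]] / n,
    total_ci = tci, hc_ci = hci
  )
}

scenario_result <- function(name, base_total, base_hc, base_sl,
                            new_total, new_hc, new_sl, total_ci, hc_ci) {
  pct <- function(new, old) {
    if (old == 0) {
      if (new == 0) 0 else NA_real_
    } else {
      (new - old) / old * 100
    }
  }
  tibble(
    scenario = name,
    pct_change_total = pct(new_total, base_total),
    pct_change_healthcare = pct(new_hc, base_hc),
    pct_change_sick_leave = pct(new_sl, base_sl),
    total_mean = new_total,
    total_ci_low = total_ci[1], total_ci_high = total_ci[2],
    healthcare_mean = new_hc,
    healthcare_ci_low = hc_ci[1], healthcare_ci_high = hc_ci[2]
  )
}

#' Switch the productivity valuation to the friction-cost method
#'
#' Convenience wrapper for the method-switch scenario: the sick-leave
#' component is multiplied by the friction factor, healthcare costs are
#' unchanged. With the published margins and the default factor 0.387 the
#' per-patient total falls by 51.6% to about 1001 euros.
#'
#' @inheritParams run_scenario
#' @return As [run_scenario()].
#' @export
#' @examples
#' run_method_switch(load_published_margins())
run_method_switch <- function(base, params = productivity_parameters()) {
  run_scenario(base,
               sensitivity_scenario("Sick leave cost based on friction method",
                                    method = "friction"),
               params)
}

#' Run a set of scenarios into one table
#'
#' Applies [run_scenario()] to each scenario in order, prepending the
#' identity base-case row — the layout of the published uncertainty table.
#'
#' @param base As in [run_scenario()].
#' @param scenarios List of [sensitivity_scenario()] objects with unique
#'   names; defaults to [default_scenarios()].
#' @param params A [productivity_parameters()].
#' @return Tibble with one row per scenario, base case first.
#' @export
#' @examples
#' scenario_table(load_published_margins())
scenario_table <- function(base, scenarios = default_scenarios(),
                           params = productivity_parameters()) {
  if (!length(scenarios)) abort("need at least one scenario")
  names <- vapply(scenarios, function(s) s$name, character(1))
  if (anyDuplicated(names)) {
    abort(paste0("duplicate scenario name(s): ",
                 paste(unique(names[duplicated(names)]), collapse = ", ")))
  }
  base_row <- run_scenario(base, sensitivity_scenario("Base case scenario"),
                           params)
  rows <- purrr::map(scenarios, run_scenario, base = base, params = params)
  bind_rows(base_row, rows)
}
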