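#' Unit-cost schedule for bottom-up costing
#'
#' Prices (2009 euros) used to value each unit of healthcare resource use
#' and each day of sick leave. Defaults are the published Swedish
#' primary-care schedule: a 25-minute general-practitioner (GP) visit at
#' 107, a 60-minute physiotherapy (PT) treatment at 50, shoulder x-ray at
#' 65, shoulder ultrasound at 124, an orthopaedic outpatient visit at 335,
#' MRI at 308, uncomplicated ambulatory shoulder surgery at 2420, and one
#' day of full sick leave from paid work at 205 (human-capital valuation:
#' mean regional income plus payroll loadings).
#'
#' The default price per filled prescription, 12.4, is the published
#' cohort's total medication cost divided by its number of prescriptions
#' (718 / 58); the source priced drugs individually without listing unit
#' prices, so a per-prescription average is the only reconstructible
#' default. Supply your own value when drug-level prices are available.
#'
#' @param gp_visit,pt_visit,xray,ultrasound Euro cost per primary-care
#'   visit or imaging examination.
#' @param medicine_per_prescription Euro cost per filled prescription.
#' @param orthopaedic_visit,mri,surgery_ambulatory Euro costs of
#'   secondary-care items, used only by [estimate_secondary_costs()].
#' @param sick_leave_day Euro cost of one full day of lost production.
#'
#' @return A named list of class `unit_cost_schedule`.
#' @seealso [productivity_parameters()], [cost_patients()]
#' @export
#' @examples
#' unit_cost_schedule()
#' unit_cost_schedule(pt_visit = 65)  # a one-way price variation
unit_cost_schedule <- function(gp_visit = 107,
                               pt_visit = 50,
                               xray = 65,
                               ultrasound = 124,
                               medicine_per_prescription = 12.4,
                               orthopaedic_visit = 335,
                               mri = 308,
                               surgery_ambulatory = 2420,
                               sick_leave_day = 205) {
  schedule <- list(
    gp_visit = gp_visit, pt_visit = pt_visit, xray = xray,
    ultrasound = ultrasound,
    medicine_per_prescription = medicine_per_prescription,
    orthopaedic_visit = orthopaedic_visit, mri = mri,
    surgery_ambulatory = surgery_ambulatory,
    sick_leave_day = sick_leave_day
  )
  bad <- names(schedule)[!vapply(schedule, function(x) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
  }, logical(1))]
  if (length(bad)) {
    abort(paste0("unit costs must be single non-negative numbers; check: ",
                 paste(bad, collapse = ", ")))
  }
  structure(schedule, class = "unit_cost_schedule")
}

#' Productivity-loss valuation parameters
#'
#' Parameters that translate absence from paid work into a euro cost.
#' Under the human-capital approach one day of full sick leave is valued
#' at the mean daily income grossed up by payroll loadings:
#' `income * (1 + social_fares_rate + indirect_tax_rate)`, i.e. what the
#' worker must produce to cover their own wage, payroll fees and indirect
#' taxes. The friction-cost method counts production loss only over the
#' friction period until a replacement is productive; it is
#' operationalised as a fixed fraction (`friction_factor`, default 0.387)
#' of the human-capital value.
#'
#' @param social_fares_rate Payroll social fees as a proportion of the
#'   wage (default 0.40).
#' @param indirect_tax_rate Indirect taxes as a proportion of the wage
#'   (default 0.28).
#' @param friction_factor Friction-cost value as a fraction of the
#'   human-capital value, in (0, 1].
#' @param valuation_method `"human_capital"` (default) or `"friction"`.
#'
#' @return A named list of class `productivity_parameters`.
#' @export
#' @examples
#' productivity_parameters()
#' productivity_parameters(valuation_method = "friction")
productivity_parameters <- function(social_fares_rate = 0.40,
                                    indirect_tax_rate = 0.28,
                                    friction_factor = 0.387,
                                    valuation_method = c("human_capital",
                                                         "friction")) {
  valuation_method <- match.arg(valuation_method)
  if (social_fares_rate < 0 || indirect_tax_rate < 0) {
    abort("social_fares_rate and indirect_tax_rate must be >= 0")
  }
  if (friction_factor <= 0 || friction_factor > 1) {
    abort("friction_factor must lie in (0, 1]")
  }
  structure(
    list(social_fares_rate = social_fares_rate,
         indirect_tax_rate = indirect_tax_rate,
         friction_factor = friction_factor,
         valuation_method = valuation_method),
    class = "productivity_parameters"
  )
}

#' Daily cost of lost production
#'
#' Values one day of absence from work under the human-capital model:
#' the mean daily income grossed up by social fees and indirect taxes,
#' `income * (1 + social_fares_rate + indirect_tax_rate)`.
#'
#' @param mean_daily_income Mean daily income in euros.
#' @param params A [productivity_parameters()] object.
#' @return Euro cost per day of full sick leave.
#' @export
#' @examples
#' daily_productivity_cost(100)           # 168 with the default loadings
#' daily_productivity_cost(122.02)        # ~205, the default day price
daily_productivity_cost <- function(mean_daily_income,
                                    params = productivity_parameters()) {
  if (!is.numeric(mean_daily_income) || any(mean_daily_income < 0)) {
    abort("mean_daily_income must be non-negative")
  }
  mean_daily_income * (1 + params$social_fares_rate + params$indirect_tax_rate)
}

#' Double a six-month cost to an annual estimate
#'
#' Costs measured over a six-month window are multiplied by 2 to estimate
#' the annual burden, on the assumption that patient through-flow is
#' stationary over the year.
#'
#' @param six_month_cost Euro cost(s) over six months; must be >= 0.
#' @return `2 * six_month_cost`.
#' @export
#' @examples
#' annualize(2069.4)  # ~4139 per patient and year
annualize <- function(six_month_cost) {
  if (!is.numeric(six_month_cost) || any(six_month_cost < 0, na.rm = TRUE)) {
    abort("six_month_cost must be non-negative")
  }
  2 * six_month_cost
}
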