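#' Published cohort cost margins
#'
#' The per-component aggregates printed for the published 204-patient
#' shoulder-pain cohort ("full") and for its 45-patient high-cost subgroup
#' (total cost > 1000 euros over six months; "highcost"): total unit
#' counts, per-patient cost mean and SD, and component total cost, for GP
#' visits, physiotherapy, x-ray, ultrasound, prescribed medication and
#' sick leave, with healthcare and overall totals. These margins are the
#' canonical input for reproducing the published headline numbers: the
#' costing model is linear, so means, confidence intervals, component
#' shares and sensitivity scenarios are all recomputable from them without
#' patient-level data.
#'
#' Note that the printed unit counts times the printed unit costs do not
#' reproduce the printed component totals exactly (differences of 10-60
#' euros, e.g. 181 GP visits x 107 = 19367 versus the printed 19429),
#' presumably rounding of unrounded per-visit costs upstream. The printed
#' totals are taken as authoritative.
#'
#' @param group `"full"` (n = 204) or `"highcost"` (n = 45).
#' @return A tibble of class `cohort_margins` with columns `component`,
#'   `mean_units`, `sd_units`, `total_units`, `cost_mean`, `cost_sd`,
#'   `total_cost`, and attribute `n` (the cohort size).
#' @export
#' @examples
#' m <- load_published_margins()
#' attr(m, "n")
#' sum(m$total_cost[m$component %in% c("healthcare_total", "sick_leave")])
load_published_margins <- function(group = c("full", "highcost")) {
  group <- match.arg(group)
  file <- switch(group, full = "margins_full_cohort.csv",
                 highcost = "margins_highcost_subgroup.csv")
  path <- system.file("extdata", file, package = "shouldercoi")
  if (!nzchar(path)) {
    abort(paste0("packaged margins fixture ", file, " is missing"))
  }
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = "cdddddd")
  required <- c(cost_components(), "healthcare_total", "total")
  if (!setequal(m$component, required) || anyDuplicated(m$component)) {
    abort(paste0("margins fixture ", file, " is corrupted: unexpected rows"))
  }
  new_cohort_margins(m, n = switch(group, full = 204L, highcost = 45L))
}

new_cohort_margins <- function(tbl, n) {
  structure(as_tibble(tbl), n = as.integer(n),
            class = c("cohort_margins", class(tbl)))
}

cost_components <- function() {
  c("gp", "pt", "xray", "ultrasound", "medicine", "sick_leave")
}

healthcare_components <- function() {
  c("gp", "pt", "xray", "ultrasound", "medicine")
}

#' @export
print.cohort_margins <- function(x, ...) {
  cat("Cohort cost margins (n = ", attr(x, "n"), ")\n", sep = "")
  NextMethod()
}

margin_total <- function(margins, component) {
  margins$total_cost[match(component, margins$component)]
}
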