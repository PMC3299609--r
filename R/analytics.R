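#' Cohort-level cost report
#'
#' Per-component descriptive statistics in the layout of the published
#' cost tables: n, per-patient mean, SD, median, quartiles, grand total, a
#' 95% normal-approximation confidence interval for the mean
#' (`mean +/- 1.96 * sd / sqrt(n)` — the construction that reproduces the
#' published intervals), and each component's share of healthcare and of
#' total cost.
#'
#' Given patient-level summaries (from [cost_patients()]) all statistics
#' are computed from the data. Given a `cohort_margins` object (printed
#' aggregates, see [load_published_margins()]) means are `total / n`, SDs are
#' as printed, and medians/quartiles are `NA` (not recoverable from
#' margins).
#'
#' @param x A tibble of patient cost summaries or a `cohort_margins`.
#' @param ... Unused.
#' @return A tibble of class `cohort_cost_report` with one row per
#'   component plus `healthcare_total` and `total` rows, and attribute `n`.
#' @export
#' @examples
#' summarize_cohort(load_published_margins())
summarize_cohort <- function(x, ...) {
  UseMethod("summarize_cohort")
}

#' @export
summarize_cohort.data.frame <- function(x, ...) {
  n <- nrow(x)
  rows <- c(healthcare_components(), "healthcare_total", "sick_leave",
            "total")
  report <- purrr::map(rows, function(comp) {
    v <- x[[comp]]
    tibble(
      component = comp,
      mean = mean(v),
      sd = if (n >= 2) sd(v) else NA_real_,
      median = median(v),
      q1 = quantile(v, 0.25, names = FALSE),
      q3 = quantile(v, 0.75, names = FALSE),
      total = sum(v)
    )
  }) |>
    purrr::list_rbind() |>
    add_ci(n) |>
    add_shares()
  structure(report, n = n, class = c("cohort_cost_report", class(report)))
}

#' @export
summarize_cohort.cohort_margins <- function(x, ...) {
  n <- attr(x, "n")
  order <- c(healthcare_components(), "healthcare_total", "sick_leave",
             "total")
  report <- x |>
    mutate(component = .data$component,
           mean = .data$total_cost / n,
           sd = .data$cost_sd,
           median = NA_real_, q1 = NA_real_, q3 = NA_real_,
           total = .data$total_cost) |>
    select("component", "mean", "sd", "median", "q1", "q3", "total") |>
    arrange(match(.data$component, order)) |>
    add_ci(n) |>
    add_shares()
  structure(report, n = n, class = c("cohort_cost_report", class(report)))
}

add_ci <- function(report, n, z = qnorm(0.975)) {
  if (n >= 2) {
    mutate(report,
           ci_low = .data$mean - z * .data$sd / sqrt(n),
           ci_high = .data$mean + z * .data$sd / sqrt(n))
  } else {
    mutate(report, ci_low = NA_real_, ci_high = NA_real_)
  }
}

add_shares <- function(report) {
  hc_total <- report$total[report$component == "healthcare_total"]
  grand <- report$total[report$component == "total"]
  mutate(
    report,
    share_healthcare = ifelse(
      .data$component %in% healthcare_components() & hc_total > 0,
      .data$total / hc_total, NA_real_),
    share_total = ifelse(
      .data$component %in% c(healthcare_components(), "sick_leave") &
        grand > 0,
      .data$total / grand, NA_real_)
  )
}

#' High-cost subgroup report
#'
#' Summarises the patients whose six-month total cost strictly exceeds a
#' threshold (1000 euros in the published analysis), and their share of
#' the cohort's total and healthcare costs. With patient-level summaries
#' the subgroup is formed by filtering; with two `cohort_margins` objects
#' (full cohort and printed subgroup) the shares are computed from the
#' printed totals.
#'
#' @param x Patient cost summaries (tibble) or full-cohort
#'   `cohort_margins`.
#' @param threshold Euro threshold (patient-level method).
#' @param subgroup_margins Subgroup `cohort_margins` (margins method).
#' @param ... Unused.
#' @return A one-row tibble: `threshold`, `n_subgroup`, `n_cohort`,
#'   `subgroup_total`, `share_total`, `subgroup_healthcare`,
#'   `share_healthcare`, with the subgroup's full
#'   [summarize_cohort()] report in attribute `report` (patient-level
#'   method only).
#' @export
#' @examples
#' subgroup_report(load_published_margins("full"),
#'                 subgroup_margins = load_published_margins("highcost"))
subgroup_report <- function(x, ...) {
  UseMethod("subgroup_report")
}

#' @export
subgroup_report.data.frame <- function(x, threshold = 1000, ...) {
  if (threshold < 0) abort("threshold must be >= 0")
  sub <- filter(x, .data$total > threshold)
  cohort_total <- sum(x$total)
  cohort_hc <- sum(x$healthcare_total)
  out <- tibble(
    threshold = threshold,
    n_subgroup = nrow(sub),
    n_cohort = nrow(x),
    subgroup_total = sum(sub$total),
    share_total = if (cohort_total > 0) sum(sub$total) / cohort_total else 0,
    subgroup_healthcare = sum(sub$healthcare_total),
    share_healthcare = if (cohort_hc > 0) {
      sum(sub$healthcare_total) / cohort_hc
    } else {
      0
    }
  )
  attr(out, "report") <- if (nrow(sub)) summarize_cohort(sub) else NULL
  out
}

#' @export
subgroup_report.cohort_margins <- function(x, threshold = 1000,
                                           subgroup_margins, ...) {
  stopifnot(inherits(subgroup_margins, "cohort_margins"))
  tibble(
    threshold = threshold,
    n_subgroup = attr(subgroup_margins, "n"),
    n_cohort = attr(x, "n"),
    subgroup_total = margin_total(subgroup_margins, "total"),
    share_total = margin_total(subgroup_margins, "total") /
      margin_total(x, "total"),
    subgroup_healthcare = margin_total(subgroup_margins, "healthcare_total"),
    share_healthcare = margin_total(subgroup_margins, "healthcare_total") /
      margin_total(x, "healthcare_total")
  )
}

#' Cost share of the most expensive patients
#'
#' Sorts per-patient totals in decreasing order and returns the share of
#' cohort cost carried by the top `ceiling(top_fraction * n)` patients —
#' e.g. the published "a fifth of the patients were responsible for 91% of
#' the total costs".
#'
#' @param totals Non-negative per-patient total costs, not all zero.
#' @param top_fraction Fraction of patients in `(0, 1]`.
#' @return Proportion of total cost in `[0, 1]`.
#' @export
#' @examples
#' concentration_share(c(1000, rep(0, 9)), 0.1)  # 1
concentration_share <- function(totals, top_fraction = 0.2) {
  if (top_fraction <= 0 || top_fraction > 1) {
    abort("top_fraction must lie in (0, 1]")
  }
  if (any(totals < 0)) abort("totals must be non-negative")
  if (all(totals == 0)) {
    abort("concentration share is undefined when every total is zero")
  }
  k <- ceiling(top_fraction * length(totals))
  sum(sort(totals, decreasing = TRUE)[seq_len(k)]) / sum(totals)
}

#' Log-cost linear regression
#'
#' Ordinary least squares of `log(cost)` on place of treatment
#' (municipality), gender and age — the published model exploring whether
#' demographics predict costs. Patients with zero cost (log undefined) are
#' excluded and counted.
#'
#' @param data Patient cost summaries joined with covariates: columns
#'   `municipality`, `sex`, `age` plus the outcome column.
#' @param outcome `"total"` or `"healthcare"`.
#' @return Object of class `coi_lm` wrapping the `lm` fit, with
#'   `n_observations` and `n_excluded`. Use [tidy.coi_lm()] /
#'   [glance.coi_lm()] for tabular access.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 3)
#' summaries <- dplyr::left_join(cost_patients(cohort), cohort$patients,
#'                               by = "patient_id")
#' fit <- fit_log_cost_regression(summaries, "total")
#' broom::tidy(fit)
fit_log_cost_regression <- function(data,
                                    outcome = c("total", "healthcare")) {
  outcome <- match.arg(outcome)
  ycol <- switch(outcome, total = "total", healthcare = "healthcare_total")
  needed <- c(ycol, "municipality", "sex", "age")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("data lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  usable <- data[data[[ycol]] > 0 & complete.cases(data[needed]), ]
  n_excluded <- nrow(data) - nrow(usable)
  if (nrow(usable) < 10) {
    abort("need at least 10 usable (positive-cost) observations")
  }
  for (covar in c("municipality", "sex")) {
    if (length(unique(usable[[covar]])) < 2) {
      abort(paste0("covariate '", covar,
                   "' is constant; the design is rank-deficient"))
    }
  }
  df <- tibble(
    log_cost = log(usable[[ycol]]),
    place = factor(usable$municipality),
    gender = factor(usable$sex),
    age = usable$age
  )
  fit <- lm(log_cost ~ place + gender + age, data = df)
  aliased <- names(which(is.na(coef(fit))))
  if (length(aliased)) {
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  structure(
    list(fit = fit, outcome = outcome,
         n_observations = nrow(usable), n_excluded = n_excluded),
    class = "coi_lm"
  )
}

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' Tidy a log-cost regression
#'
#' @param x A `coi_lm` from [fit_log_cost_regression()].
#' @param ... Passed to [broom::tidy()] for `lm`.
#' @return Coefficient tibble (term, estimate, std.error, statistic,
#'   p.value).
#' @export
tidy.coi_lm <- function(x, ...) {
  broom::tidy(x$fit, ...)
}

#' One-row summary of a log-cost regression
#'
#' @param x A `coi_lm`.
#' @param ... Passed to [broom::glance()] for `lm`.
#' @return One-row tibble with fit statistics plus `n_observations`,
#'   `n_excluded` and `outcome`.
#' @export
glance.coi_lm <- function(x, ...) {
  broom::glance(x$fit, ...) |>
    mutate(n_observations = x$n_observations,
           n_excluded = x$n_excluded,
           outcome = x$outcome)
}

#' @export
print.coi_lm <- function(x, ...) {
  cat("Log-cost regression (outcome: ", x$outcome, "), n = ",
      x$n_observations, " (", x$n_excluded, " zero-cost excluded)\n",
      sep = "")
  print(tidy.coi_lm(x))
  invisible(x)
}
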