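#' Write / read an EPR cohort as delimited text
#'
#' A cohort is stored as four CSV tables with ISO-8601 dates:
#' `patients.csv`, `visits.csv`, `sickleave.csv` and `events.csv`.
#'
#' @param cohort An `epr_cohort`.
#' @param dir Directory to write into (created if needed).
#' @param window Measurement window to attach on read; `read_cohort()`
#'   defaults to the span of the observed dates when not supplied.
#' @return `write_cohort()` returns the four file paths invisibly;
#'   `read_cohort()` returns an `epr_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("patients", "visits", "sickleave", "events")
  paths <- file.path(dir, paste0(tables, ".csv"))
  purrr::walk2(tables, paths,
               function(tab, path) readr::write_csv(cohort[[tab]], path,
                                                    progress = FALSE))
  invisible(setNames(paths, tables))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, window = NULL) {
  read1 <- function(name, cols) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) abort(paste0("missing cohort table: ", path))
    readr::read_csv(path, col_types = cols, progress = FALSE)
  }
  patients <- read1("patients", readr::cols(
    patient_id = "c", age = "d", sex = "c", municipality = "c",
    .default = readr::col_guess()
  ))
  visits <- read1("visits", readr::cols(patient_id = "c", date = "D",
                                        provider = "c", code = "c"))
  sickleave <- read1("sickleave", readr::cols(patient_id = "c", start = "D",
                                              end = "D", grade = "d"))
  events <- read1("events", readr::cols(patient_id = "c", date = "D",
                                        type = "c", detail = "c"))
  validate_cohort_tables(patients, visits, sickleave, events)
  window <- window %||% range(c(visits$date, sickleave$start, sickleave$end))
  new_epr_cohort(patients, visits, sickleave, events,
                 window = as_window(window), config = NULL)
}

validate_cohort_tables <- function(patients, visits, sickleave, events) {
  check_cols <- function(tbl, name, cols) {
    miss <- setdiff(cols, names(tbl))
    if (length(miss)) {
      abort(paste0(name, ".csv lacks column(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  check_cols(patients, "patients",
             c("patient_id", "age", "sex", "municipality"))
  check_cols(visits, "visits", c("patient_id", "date", "provider", "code"))
  check_cols(sickleave, "sickleave",
             c("patient_id", "start", "end", "grade"))
  check_cols(events, "events", c("patient_id", "date", "type"))
  if (any(!visits$provider %in% c("GP", "PT"))) {
    bad <- which(!visits$provider %in% c("GP", "PT"))[1]
    abort(paste0("visits.csv row ", bad,
                 ", column provider: must be GP or PT"))
  }
  if (nrow(sickleave) && any(sickleave$start > sickleave$end)) {
    bad <- which(sickleave$start > sickleave$end)[1]
    abort(paste0("sickleave.csv row ", bad, ", column end: end before start"))
  }
  if (any(patients$age < 0 | patients$age > 120)) {
    bad <- which(patients$age < 0 | patients$age > 120)[1]
    abort(paste0("patients.csv row ", bad, ", column age: outside [0, 120]"))
  }
  invisible(TRUE)
}

#' Assemble a pipeline configuration
#'
#' Bundles every tunable of the pipeline: either a synthetic-cohort block
#' or a directory of cohort tables (exactly one of the two), the unit-cost
#' schedule, productivity parameters, episode rule, subgroup threshold and
#' sensitivity scenarios. Use [read_pipeline_config()] to load the same
#' structure from a YAML or JSON file.
#'
#' @param synthetic A [cohort_config()], or `NULL` when reading tables.
#' @param input_dir Directory holding the four cohort tables, or `NULL`.
#' @param schedule A [unit_cost_schedule()].
#' @param params A [productivity_parameters()].
#' @param grade_policy See [sick_leave_day_equivalents()].
#' @param gap_days,holiday_window Episode rule, see [build_episode()].
#' @param subgroup_threshold Euro threshold of the high-cost subgroup.
#' @param scenarios List of [sensitivity_scenario()] objects.
#' @param seed Seed for cohort generation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = cohort_config(),
                            input_dir = NULL,
                            schedule = unit_cost_schedule(),
                            params = productivity_parameters(),
                            grade_policy = "graded_weighting",
                            gap_days = 31,
                            holiday_window = NULL,
                            subgroup_threshold = 1000,
                            scenarios = default_scenarios(),
                            seed = NULL) {
  if (is.null(synthetic) == is.null(input_dir)) {
    abort("provide exactly one of `synthetic` (a cohort_config) or `input_dir`")
  }
  structure(
    list(synthetic = synthetic, input_dir = input_dir, schedule = schedule,
         params = params, grade_policy = grade_policy, gap_days = gap_days,
         holiday_window = holiday_window,
         subgroup_threshold = subgroup_threshold, scenarios = scenarios,
         seed = seed %||% if (!is.null(synthetic)) synthetic$seed else 1L),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised top-level keys: `synthetic` (arguments to [cohort_config()]),
#' `input_dir`, `unit_costs` (arguments to [unit_cost_schedule()]),
#' `productivity` (arguments to [productivity_parameters()]), `episode`
#' (`gap_days`, `holiday_window`), `grade_policy`, `subgroup_threshold`,
#' `scenarios` (a list of `{name, multipliers, method}` entries) and
#' `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  synthetic <- if (!is.null(raw$synthetic)) {
    args <- raw$synthetic
    for (f in c("window", "holiday_window")) {
      if (!is.null(args[[f]])) args[[f]] <- as.Date(unlist(args[[f]]))
    }
    for (f in c("category_weights", "imaging_probs")) {
      if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
    }
    do.call(cohort_config, args)
  }
  scenarios <- if (!is.null(raw$scenarios)) {
    purrr::map(raw$scenarios, function(s) {
      sensitivity_scenario(s$name, unlist(s$multipliers) %||% numeric(),
                           s$method)
    })
  } else {
    default_scenarios()
  }
  pipeline_config(
    synthetic = synthetic,
    input_dir = raw$input_dir,
    schedule = do.call(unit_cost_schedule, raw$unit_costs %||% list()),
    params = do.call(productivity_parameters, raw$productivity %||% list()),
    grade_policy = raw$grade_policy %||% "graded_weighting",
    gap_days = raw$episode$gap_days %||% 31,
    holiday_window = if (!is.null(raw$episode$holiday_window)) {
      as.Date(unlist(raw$episode$holiday_window))
    },
    subgroup_threshold = raw$subgroup_threshold %||% 1000,
    scenarios = scenarios,
    seed = raw$seed
  )
}

#' Simulate a cohort and write it to disk
#'
#' Generates the synthetic cohort described by the configuration, writes
#' the four delimited-text tables plus a `provenance.json` sidecar (seed,
#' configuration hash, package version) and returns the cohort.
#'
#' @param config A [pipeline_config()] with a `synthetic` block.
#' @param out_dir Output directory.
#' @param seed Overrides the configured seed.
#' @return The generated `epr_cohort`, invisibly.
#' @export
coi_simulate <- function(config, out_dir, seed = config$seed) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$synthetic)) {
    abort("coi_simulate() needs a configuration with a synthetic block")
  }
  cohort <- generate_cohort(config$synthetic, seed = seed)
  write_cohort(cohort, out_dir)
  provenance <- list(
    seed = seed,
    config_hash = rlang::hash(config$synthetic),
    package_version = as.character(utils::packageVersion("shouldercoi")),
    n_patients = nrow(cohort$patients),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

#' Run the full cost-of-illness analysis
#'
#' Ties the stages together: cohort (generated or read from disk) ->
#' inclusion and episode construction -> bottom-up costing ->
#' cohort statistics, high-cost subgroup and concentration -> sensitivity
#' scenarios -> annualized totals.
#'
#' @param config A [pipeline_config()].
#' @param seed Overrides the configured seed for synthetic cohorts.
#' @return A list of class `coi_analysis`: `cohort`, `summaries`
#'   (patient-level costs joined with demographics), `episodes`,
#'   `episode_table` (duration-band counts), `report`
#'   (full-cohort [summarize_cohort()]), `subgroup`, `concentration_top20`,
#'   `sensitivity` (the [scenario_table()]), `annual_mean_total`, and
#'   `secondary_care_cost` (estimated from referred/operated patients and
#'   one MRI per three referrals, rounded).
#' @export
#' @examples
#' res <- coi_analyze(pipeline_config(synthetic = cohort_config(
#'   n_patients = 40)), seed = 2)
#' res$report
coi_analyze <- function(config = pipeline_config(), seed = config$seed) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$synthetic)) {
    generate_cohort(config$synthetic, seed = seed)
  } else {
    read_cohort(config$input_dir)
  }
  window <- cohort$window
  holiday <- config$holiday_window %||% default_holiday_window(window)

  patients <- include_patients(cohort$patients, cohort$visits, window)
  episodes <- build_episodes(cohort$visits, patients, window,
                             gap_days = config$gap_days,
                             holiday_window = holiday)
  episode_table <- episodes |>
    count(.data$duration_category, .drop = FALSE) |>
    mutate(proportion = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0)

  costs <- cost_patients(cohort, config$schedule, config$params,
                         config$grade_policy, window)
  summaries <- costs |>
    left_join(patients, by = "patient_id") |>
    filter(.data$included)

  report <- summarize_cohort(select(summaries, -"included"))
  subgroup <- subgroup_report(summaries,
                              threshold = config$subgroup_threshold)
  concentration <- if (nrow(summaries) && any(summaries$total > 0)) {
    concentration_share(summaries$total, 0.2)
  } else {
    NA_real_
  }
  sens <- scenario_table(select(summaries, dplyr::all_of(names(costs))),
                         config$scenarios, config$params)
  n_referred <- sum(patients$referred %||% logical(0))
  n_surgery <- sum(patients$surgery %||% logical(0))
  secondary <- estimate_secondary_costs(
    n_referred, round(n_referred / 2.9), n_surgery, config$schedule
  )
  mean_total <- report$mean[report$component == "total"]

  structure(
    list(cohort = cohort, patients = patients, summaries = summaries,
         episodes = episodes, episode_table = episode_table,
         report = report, subgroup = subgroup,
         concentration_top20 = concentration, sensitivity = sens,
         annual_mean_total = annualize(mean_total),
         secondary_care_cost = secondary,
         mode = if (!is.null(config$synthetic)) "synthetic" else "tables"),
    class = "coi_analysis"
  )
}

#' Reproduce the published aggregate analysis from printed margins
#'
#' Runs the margins-mode pipeline: cohort statistics with confidence
#' intervals, component shares, high-cost subgroup shares, the sensitivity
#' table and the annualized mean total cost, all computed from the
#' packaged printed aggregates rather than patient-level data.
#'
#' @param scenarios List of scenarios, default [default_scenarios()].
#' @param params A [productivity_parameters()].
#' @return A list: `report`, `subgroup`, `sensitivity`,
#'   `annual_mean_total`, `mode = "margins"`.
#' @export
#' @examples
#' res <- coi_analyze_margins()
#' res$sensitivity
coi_analyze_margins <- function(scenarios = default_scenarios(),
                                params = productivity_parameters()) {
  margins <- load_published_margins("full")
  list(
    report = summarize_cohort(margins),
    subgroup = subgroup_report(margins,
                               subgroup_margins = load_published_margins("highcost")),
    sensitivity = scenario_table(margins, scenarios, params),
    annual_mean_total = annualize(margin_total(margins, "total") /
                                    attr(margins, "n")),
    mode = "margins"
  )
}

#' Write an analysis result bundle as CSV and JSON
#'
#' @param result A `coi_analysis` (or the list from
#'   [coi_analyze_margins()]).
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  write1 <- function(tbl, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tbl, path, progress = FALSE)
    paths <<- c(paths, path)
  }
  if (!is.null(result$report)) write1(result$report, "cohort_report")
  if (!is.null(result$subgroup)) write1(result$subgroup, "subgroup_report")
  if (!is.null(result$sensitivity)) {
    write1(render_sensitivity(result$sensitivity), "sensitivity_table")
  }
  if (!is.null(result$episode_table)) {
    write1(result$episode_table, "episode_durations")
  }
  summary_json <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(mode = result$mode,
         annual_mean_total = round_half_up(result$annual_mean_total),
         concentration_top20 = result$concentration_top20,
         secondary_care_cost = result$secondary_care_cost),
    summary_json, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(paths, summary_json))
}

# half-up euro rounding for rendered reports (R's round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# rendered sensitivity table: whole euros, one-decimal percentages
render_sensitivity <- function(sens) {
  sens |>
    mutate(across(c("pct_change_total", "pct_change_healthcare",
                    "pct_change_sick_leave"),
                  ~ round_half_up(.x, 1)),
           across(c("total_mean", "total_ci_low", "total_ci_high",
                    "healthcare_mean", "healthcare_ci_low",
                    "healthcare_ci_high"),
                  round_half_up))
}

#' @export
print.coi_analysis <- function(x, ...) {
  cat("Cost-of-illness analysis (", x$mode, " mode)\n",
      "included patients: ", nrow(x$summaries), "\n",
      "annual mean total cost: ",
      round_half_up(x$annual_mean_total), "\n", sep = "")
  print(x$report)
  invisible(x)
}
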