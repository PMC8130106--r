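#' Read an item catalogue CSV
#'
#' Expected columns: `name`, `unit_cost_eur` (dot decimal separator, no
#' thousands separators). Validation errors name the offending file.
#'
#' @param path CSV path.
#' @return an [item_catalogue()].
#' @export
read_catalogue <- function(path) {
  df <- read_checked(path, c("name", "unit_cost_eur"))
  tryCatch(item_catalogue(df$name, as.numeric(df$unit_cost_eur)),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Read a tariff schedule CSV
#'
#' Columns `start_date`, `end_date` (inclusive last day; blank for the
#' open-ended final period), `daily_rate_eur`. Contiguity violations are
#' reported with the gap date.
#'
#' @param path CSV path.
#' @return a [tariff_schedule()].
#' @export
read_tariff <- function(path) {
  df <- read_checked(path, c("start_date", "end_date", "daily_rate_eur"))
  end <- as.character(df$end_date)
  end[is.na(end) | !nzchar(end)] <- NA
  tryCatch(
    tariff_schedule(parse_dates(df$start_date, path),
                    as.Date(ifelse(is.na(end), NA, end)),
                    as.numeric(df$daily_rate_eur)),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' Read a cohort roster CSV
#'
#' Columns `patient_id`, `status` (`new`/`prevalent`), `entry_date`,
#' `end_date` (exclusive), ISO-8601 dates.
#'
#' @param path CSV path.
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- read_checked(path, c("patient_id", "status", "entry_date", "end_date"))
  df$entry_date <- parse_dates(df$entry_date, path)
  df$end_date <- parse_dates(df$end_date, path)
  if (anyDuplicated(df$patient_id)) {
    stop(path, ": duplicated patient_id", call. = FALSE)
  }
  bad <- setdiff(unique(df$status), c("new", "prevalent"))
  if (length(bad)) stop(path, ": unknown status ", bad[1], call. = FALSE)
  if (any(df$end_date <= df$entry_date)) {
    stop(path, ": follow-up must satisfy entry_date < end_date", call. = FALSE)
  }
  df
}

#' Read a usage ledger CSV
#'
#' Columns `patient_id`, `item`, `date`, `quantity`.
#'
#' @param path CSV path.
#' @param cohort optional cohort data frame; if given, events are
#'   checked to lie inside each patient's follow-up.
#' @param catalogue optional [item_catalogue()]; if given, item names
#'   are checked against it.
#' @return validated usage data frame.
#' @export
read_usage <- function(path, cohort = NULL, catalogue = NULL) {
  df <- read_checked(path, c("patient_id", "item", "date", "quantity"))
  df$date <- parse_dates(df$date, path)
  df$quantity <- as.integer(df$quantity)
  if (any(is.na(df$quantity)) || any(df$quantity < 1)) {
    stop(path, ": quantities must be positive integers", call. = FALSE)
  }
  if (!is.null(catalogue)) {
    unknown <- setdiff(unique(df$item), catalogue$name)
    if (length(unknown)) {
      stop(path, ": unknown item ", unknown[1], call. = FALSE)
    }
  }
  if (!is.null(cohort)) validate_usage(df, cohort)
  df
}

#' Read a budget-impact projection CSV
#'
#' Columns `year`, `traditional_eur`, `alternative_eur` and optionally
#' the printed `difference_eur` / `difference_pct` columns, which are
#' verified against recomputation (see [projection_table()]).
#'
#' @param path CSV path.
#' @return a `projection_table`.
#' @export
read_projection <- function(path) {
  df <- read_checked(path, c("year", "traditional_eur", "alternative_eur"))
  tryCatch(
    projection_table(as.integer(df$year),
                     as.numeric(df$traditional_eur),
                     as.numeric(df$alternative_eur),
                     difference_eur = if ("difference_eur" %in% names(df))
                       as.numeric(df$difference_eur),
                     difference_pct = if ("difference_pct" %in% names(df))
                       as.numeric(df$difference_pct)),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' Read long-form survey counts
#'
#' Columns `question`, `response`, `system`, `count`.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_survey <- function(path) {
  df <- read_checked(path, c("question", "response", "system", "count"))
  df$count <- as.integer(df$count)
  if (any(is.na(df$count)) || any(df$count < 0)) {
    stop(path, ": counts must be non-negative integers", call. = FALSE)
  }
  df
}

read_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(path, ": missing required columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

parse_dates <- function(x, path) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop(path, ": malformed ISO-8601 date '", x[which(is.na(d))[1]], "'",
         call. = FALSE)
  }
  d
}

#' Write a generated cohort to the CSV dialects the pipeline reads
#'
#' @param cohort a `cpap_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written (`cohort.csv`, `usage.csv`,
#'   `survey.csv`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cpap_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cohort.csv", "usage.csv", "survey.csv"))
  utils::write.csv(cohort$patients, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$usage, paths[2], row.names = FALSE, quote = FALSE)
  sv <- do.call(rbind, lapply(names(cohort$survey), function(sys) {
    data.frame(question = "satisfaction", response = names(cohort$survey[[sys]]),
               system = sys, count = as.integer(cohort$survey[[sys]]))
  }))
  utils::write.csv(sv, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Run the full comparative cost analysis
#'
#' Orchestrates every stage on the packaged study inputs (or overrides):
#' microcosting of the internalized arm, comparison against the
#' contracted outsourced total, per-device-day and per-patient metrics,
#' budget-impact table verification, device-price sensitivity scenarios
#' and survey statistics. Every assumption used (nursing workdays,
#' rounding modes, exogenous outsourced total) is recorded in the
#' report's `assumptions` element, and every rounded figure is
#' accompanied by its unrounded value.
#'
#' @param catalogue an [item_catalogue()].
#' @param usage_quantities data frame `item`, `quantity`.
#' @param aggregates list as returned by [study_aggregates()].
#' @param projection a `projection_table`, or `NULL` to skip that stage.
#' @param survey long-form survey data frame, or `NULL` to skip.
#' @param scenario_multipliers device-price factors for the sensitivity
#'   suite.
#' @param device_fraction device-attributable fraction of each
#'   alternative-arm year (see [scenario_suite()]).
#' @param out_dir if non-`NULL`, writes `report.json`, `report.txt`,
#'   `projection.csv` and `scenarios.csv` there.
#' @return the report as a nested list (class `cpap_report`).
#' @export
run_full_analysis <- function(catalogue = study_catalogue(),
                              usage_quantities = study_usage_quantities(),
                              aggregates = study_aggregates(),
                              projection = study_projection(),
                              survey = study_survey(),
                              scenario_multipliers = c(1, 1.25, 1.5),
                              device_fraction = NULL,
                              out_dir = NULL) {
  cons <- consumables_total(catalogue, usage_quantities)
  nurse <- nursing_cost(aggregates$nursing_workdays,
                        aggregates$nursing_daily_wage)
  internal <- internal_total(cons$total, nurse)
  cmp <- cost_comparison(internal, aggregates$outsourced_total,
                         aggregates$patient_days,
                         aggregates$n_new, aggregates$n_prevalent,
                         aggregates$subgroup_savings)
  if (is.null(device_fraction)) {
    dev_sub <- cons$by_item$subtotal_eur[cons$by_item$name == "CPAP"]
    device_fraction <- if (length(dev_sub)) dev_sub / eur(internal) else 0
  }
  report <- list(
    assumptions = list(
      nursing_workdays = aggregates$nursing_workdays,
      nursing_daily_wage_eur = eur(aggregates$nursing_daily_wage),
      outsourced_total_eur = eur(aggregates$outsourced_total),
      outsourced_total_source = "contracted per-device-day billing (exogenous)",
      device_day_rounding = "half_up",
      per_patient_rounding = "truncate",
      device_fraction = device_fraction),
    microcosting = list(
      by_item = cons$by_item,
      consumables_total_eur = eur(cons$total),
      nursing_cost_eur = eur(nurse),
      internal_total_eur = eur(internal)),
    comparison = comparison_report(cmp))
  if (!is.null(projection)) {
    tc <- table_consistency(projection)
    report$budget_impact <- list(
      rows = as.data.frame(projection),
      total_traditional_eur = eur(tc$total_traditional),
      total_alternative_eur = eur(tc$total_alternative),
      total_difference_eur = eur(tc$total_difference),
      total_difference_pct = tc$total_difference_pct,
      flags = tc$flags)
    report$sensitivity <- scenario_suite(projection, scenario_multipliers,
                                         device_fraction)
  }
  if (!is.null(survey) && nrow(survey) > 0L) {
    sat <- survey_question_table(survey, "satisfaction")
    qual <- survey_question_table(survey, "quality")
    pref_rows <- survey[survey$question == "preference", ]
    report$survey <- list(
      satisfaction = list(
        full = strip_expected(suppressWarnings(chi_square_test(sat))),
        binary = strip_expected(suppressWarnings(
          chi_square_test(sat, collapse = "binary")))),
      quality = strip_expected(suppressWarnings(
        suppressMessages(chi_square_test(qual)))),
      preference = preference_summary(
        stats::setNames(pref_rows$count, pref_rows$response)))
  }
  class(report) <- "cpap_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

strip_expected <- function(res) res[setdiff(names(res), "expected")]

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(report$budget_impact)) {
    utils::write.csv(report$budget_impact$rows,
                     file.path(out_dir, "projection.csv"), row.names = FALSE)
  }
  if (!is.null(report$sensitivity)) {
    utils::write.csv(report$sensitivity,
                     file.path(out_dir, "scenarios.csv"), row.names = FALSE)
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.cpap_report <- function(x, ...) {
  cat("== CPAP provision cost analysis ==\n\n")
  cat("Internalized microcosting:\n")
  print(x$microcosting$by_item, row.names = FALSE)
  cat(sprintf("  consumables total: %.2f\n  nursing: %.2f\n  internal total: %.2f\n",
              x$microcosting$consumables_total_eur,
              x$microcosting$nursing_cost_eur,
              x$microcosting$internal_total_eur))
  tc <- x$comparison$totals
  cat(sprintf("\nComparison: outsourced %.2f - internal %.2f = saving %.2f\n",
              tc$outsourced_eur, tc$internal_eur, tc$direct_saving_eur))
  cat(sprintf("  per device-day: %.2f (internal) vs %.2f (outsourced)\n",
              x$comparison$per_device_day$internal$eur,
              x$comparison$per_device_day$outsourced$eur))
  if (!is.null(x$comparison$subgroups)) {
    cat(sprintf("  per-patient saving: new %.2f, prevalent %.2f\n",
                x$comparison$subgroups$new$per_patient$eur,
                x$comparison$subgroups$prevalent$per_patient$eur))
  }
  if (!is.null(x$budget_impact)) {
    cat(sprintf("\nBudget impact: total difference %.2f (%.2f%%)\n",
                x$budget_impact$total_difference_eur,
                x$budget_impact$total_difference_pct))
  }
  if (!is.null(x$sensitivity)) {
    cat("\nDevice-price sensitivity:\n")
    print(x$sensitivity, row.names = FALSE)
  }
  if (!is.null(x$survey)) {
    cat(sprintf("\nSurvey: satisfaction chi-square p = %.2g (full), %.2g (binary); preference for internalized %.1f%%\n",
                x$survey$satisfaction$full$p_value,
                x$survey$satisfaction$binary$p_value,
                x$survey$preference$pct[x$survey$preference$option ==
                                          "internalized_system"]))
  }
  invisible(x)
}
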