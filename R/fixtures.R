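#' Packaged study inputs
#'
#' Accessors for the study's printed inputs, shipped as plain CSV under
#' `inst/extdata`: the direct-cost item catalogue (retail prices, VAT
#' included), the consumption quantities over follow-up, the three-rate
#' rental tariff schedule, the health-area budget-impact table and the
#' satisfaction-survey counts. Cohort aggregates that cannot be
#' re-derived from per-patient data (which were never published) are
#' exposed by [study_aggregates()] as exogenous inputs.
#'
#' @name study_fixtures
NULL

extdata <- function(file) {
  path <- system.file("extdata", file, package = "cpapcost")
  if (!nzchar(path)) stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

#' @describeIn study_fixtures direct-cost item catalogue.
#' @export
study_catalogue <- function() read_catalogue(extdata("catalogue.csv"))

#' @describeIn study_fixtures item quantities used over follow-up
#'   (data frame `item`, `quantity`).
#' @export
study_usage_quantities <- function() {
  u <- utils::read.csv(extdata("usage_quantities.csv"),
                       stringsAsFactors = FALSE)
  u$quantity <- as.integer(u$quantity)
  u
}

#' @describeIn study_fixtures the three-rate rental tariff schedule
#'   (€ 1.10 to end January 2014, € 0.86 to 6 July 2014, € 0.65 onwards).
#' @export
study_tariff <- function() read_tariff(extdata("tariff.csv"))

#' @describeIn study_fixtures health-area budget-impact projection,
#'   years 2015-2019, as a `projection_table`.
#' @export
study_projection <- function() read_projection(extdata("projection_health_area.csv"))

#' @describeIn study_fixtures satisfaction-survey counts in long form.
#' @export
study_survey <- function() read_survey(extdata("survey.csv"))

#' @describeIn study_fixtures cohort aggregates used as exogenous
#'   inputs: patient counts, patient-days, the contracted outsourced
#'   total, nursing wage/workdays and the published subgroup savings.
#' @export
study_aggregates <- function() {
  list(n_patients = 21L, n_new = 4L, n_prevalent = 17L,
       patient_days = 23046L,
       outsourced_total = money(22781.18),
       nursing_daily_wage = money(153.51),
       nursing_workdays = 6L,
       subgroup_savings = stats::setNames(money(c(3065.38, 12890.69)),
                                          c("new", "prevalent")),
       health_area_population = 135136L,
       device_lifetime_years = 5L)
}

#' Survey long-form counts as a contingency table for one question
#'
#' @param survey long-form survey data frame from [study_survey()].
#' @param question question id (`"satisfaction"` or `"quality"`).
#' @return a [contingency_table()] with systems as columns, preserving
#'   the response-category order of the file.
#' @export
survey_question_table <- function(survey, question) {
  q <- survey[survey$question == question, , drop = FALSE]
  if (nrow(q) == 0L) stop("no rows for question ", question, call. = FALSE)
  responses <- unique(q$response)
  systems <- unique(q$system)
  m <- matrix(0L, nrow = length(responses), ncol = length(systems),
              dimnames = list(responses, systems))
  m[cbind(match(q$response, responses), match(q$system, systems))] <- q$count
  contingency_table(m)
}
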