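#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure of a small prospective CPAP
#' internalization cohort: patients recruited uniformly over a
#' recruitment window, followed to a common administrative end date
#' (with optional exponential dropout), one device issued at entry, and
#' consumable replacements arriving as independent Poisson processes at
#' per-patient-year rates. Defaults mirror the study conditions: 4 new +
#' 17 prevalent patients, recruitment October–December 2013, follow-up
#' through October 2016, no dropout.
#'
#' @param n_new,n_prevalent patient counts by status at entry.
#' @param recruitment_start,recruitment_end recruitment window, half-open
#'   `[start, end)`.
#' @param follow_up_end administrative censoring date (exclusive).
#' @param dropout_rate per-patient-year exponential dropout hazard
#'   (default 0: the study reported none).
#' @param replacement_rates named numeric vector, expected replacement
#'   events per patient-year per item; `NULL` means calibrate to the
#'   packaged consumption table via [calibrate_to_table1()] at
#'   generation time. The item `"CPAP"` is never a rate: one device is
#'   issued deterministically at entry.
#' @param survey_probs list with elements `internalized` and `external`,
#'   each a named probability vector over response categories; defaults
#'   reproduce the observed satisfaction distribution.
#' @param seed integer; identical seed + config give identical cohorts.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(n_new = 4, n_prevalent = 17,
                          recruitment_start = "2013-10-01",
                          recruitment_end = "2014-01-01",
                          follow_up_end = "2016-11-01",
                          dropout_rate = 0,
                          replacement_rates = NULL,
                          survey_probs = NULL,
                          seed = 1L) {
  rs <- as.Date(recruitment_start); re <- as.Date(recruitment_end)
  fe <- as.Date(follow_up_end)
  if (re <= rs) stop("recruitment window must satisfy start < end", call. = FALSE)
  if (fe <= re) {
    stop("follow_up_end must fall after the recruitment window", call. = FALSE)
  }
  if (n_new < 0 || n_prevalent < 0) stop("patient counts must be >= 0",
                                         call. = FALSE)
  if (dropout_rate < 0) stop("dropout_rate must be >= 0", call. = FALSE)
  if (!is.null(replacement_rates)) {
    if (is.null(names(replacement_rates)) || any(replacement_rates < 0)) {
      stop("replacement_rates must be a named, non-negative vector",
           call. = FALSE)
    }
  }
  if (is.null(survey_probs)) {
    survey_probs <- list(
      internalized = c(very_satisfied = 15, satisfied = 6,
                       dissatisfied = 0, very_dissatisfied = 0) / 21,
      external = c(very_satisfied = 2, satisfied = 12,
                   dissatisfied = 2, very_dissatisfied = 1) / 17)
  }
  structure(list(n_new = as.integer(n_new),
                 n_prevalent = as.integer(n_prevalent),
                 recruitment_start = rs, recruitment_end = re,
                 follow_up_end = fe,
                 dropout_rate = dropout_rate,
                 replacement_rates = replacement_rates,
                 survey_probs = survey_probs,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Expected patient-years of follow-up under a config
#'
#' Deterministic expectation: a uniform entry date over the recruitment
#' window followed to the censoring date (dropout shortens follow-up by
#' the usual exponential-censoring factor).
#'
#' @param config a [cohort_config()].
#' @return expected total patient-years across the cohort.
#' @export
expected_patient_years <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_new + config$n_prevalent
  win_days <- as.numeric(config$recruitment_end - config$recruitment_start)
  mean_fu_days <- as.numeric(config$follow_up_end - config$recruitment_start) -
    (win_days - 1) / 2  # mean over entry days start .. end-1
  if (config$dropout_rate > 0) {
    lam <- config$dropout_rate / 365.25
    mean_fu_days <- (1 - exp(-lam * mean_fu_days)) / lam
  }
  n * mean_fu_days / 365.25
}

#' Calibrate replacement rates to a target consumption table
#'
#' Sets each item's Poisson rate so the expected event count over the
#' cohort's expected patient-years equals the target quantity. The
#' device itself ("CPAP") is excluded: it is issued at entry, so its
#' count always equals the number of patients.
#'
#' @param config a [cohort_config()].
#' @param targets named integer vector of target total quantities;
#'   defaults to the packaged consumption table quantities.
#' @return the config with `replacement_rates` filled in.
#' @export
calibrate_to_table1 <- function(config, targets = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(targets)) {
    u <- study_usage_quantities()
    targets <- stats::setNames(u$quantity, u$item)
  }
  py <- expected_patient_years(config)
  if (py <= 0) stop("cohort has zero expected patient-years; cannot calibrate",
                    call. = FALSE)
  targets <- targets[names(targets) != "CPAP"]
  config$replacement_rates <- targets / py
  config
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic cohort, usage ledger and survey counts
#'
#' Fully reproducible under `config$seed`. Entry dates are uniform over
#' the recruitment window; each patient receives one CPAP (with its
#' tubing) at entry; replacement events per item are Poisson with the
#' configured per-patient-year rate, dated uniformly within the
#' patient's follow-up; survey counts are multinomial draws from the
#' configured response distributions (prevalent patients also answer for
#' the external system they experienced).
#'
#' @param config a [cohort_config()]; if `replacement_rates` is `NULL`
#'   it is first calibrated via [calibrate_to_table1()].
#' @return a `cpap_cohort` list with elements `patients` (data frame:
#'   `patient_id`, `status`, `entry_date`, `end_date`), `usage`
#'   (`patient_id`, `item`, `date`, `quantity`), and `survey` (list of
#'   per-system response count vectors).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_new + config$n_prevalent
  empty_usage <- data.frame(patient_id = character(), item = character(),
                            date = as.Date(character()), quantity = integer())
  if (n == 0L) {
    return(structure(list(
      patients = data.frame(patient_id = character(), status = character(),
                            entry_date = as.Date(character()),
                            end_date = as.Date(character())),
      usage = empty_usage,
      survey = list(), config = config), class = "cpap_cohort"))
  }
  if (is.null(config$replacement_rates)) {
    config <- calibrate_to_table1(config)
  }
  with_seed(config$seed, {
    win_days <- as.integer(config$recruitment_end - config$recruitment_start)
    entry <- config$recruitment_start +
      sample.int(win_days, n, replace = TRUE) - 1L
    end <- rep(config$follow_up_end, n)
    if (config$dropout_rate > 0) {
      t_drop <- stats::rexp(n, rate = config$dropout_rate / 365.25)
      end <- pmin(end, entry + ceiling(pmax(t_drop, 1)))
    }
    patients <- data.frame(
      patient_id = sprintf("P%02d", seq_len(n)),
      status = c(rep("new", config$n_new), rep("prevalent", config$n_prevalent)),
      entry_date = entry, end_date = end,
      stringsAsFactors = FALSE)
    fu_days <- as.integer(patients$end_date - patients$entry_date)
    # device (with tubing) issued at entry
    usage <- data.frame(patient_id = patients$patient_id, item = "CPAP",
                        date = patients$entry_date, quantity = 1L,
                        stringsAsFactors = FALSE)
    rates <- config$replacement_rates
    for (item in names(rates)) {
      k <- stats::rpois(n, rates[[item]] * fu_days / 365.25)
      who <- rep(seq_len(n), k)
      if (length(who)) {
        offs <- unlist(lapply(seq_len(n), function(i) {
          if (k[i] == 0L) return(integer(0))
          sample.int(fu_days[i], k[i], replace = TRUE) - 1L
        }))
        usage <- rbind(usage, data.frame(
          patient_id = patients$patient_id[who], item = item,
          date = patients$entry_date[who] + offs,
          quantity = 1L, stringsAsFactors = FALSE))
      }
    }
    usage <- usage[order(usage$patient_id, usage$date, usage$item), ]
    rownames(usage) <- NULL
    pr <- config$survey_probs
    survey <- list(
      internalized = stats::setNames(as.integer(
        stats::rmultinom(1, n, pr$internalized)), names(pr$internalized)),
      external = stats::setNames(as.integer(
        stats::rmultinom(1, max(config$n_prevalent, 0), pr$external)),
        names(pr$external)))
    structure(list(patients = patients, usage = usage, survey = survey,
                   config = config), class = "cpap_cohort")
  })
}

#' @export
print.cpap_cohort <- function(x, ...) {
  cat("Synthetic CPAP cohort: ", nrow(x$patients), " patients (",
      sum(x$patients$status == "new"), " new, ",
      sum(x$patients$status == "prevalent"), " prevalent), ",
      sum(as.integer(x$patients$end_date - x$patients$entry_date)),
      " patient-days, ", nrow(x$usage), " usage events\n", sep = "")
  invisible(x)
}
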