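#' Piecewise-constant daily rental tariff schedule
#'
#' The outsourced provider bills a flat rate per device and day, but the
#' contracted rate changed twice during the study follow-up, so accrual
#' runs over a dated, piecewise-constant schedule. Periods are held
#' half-open `[start, end)`: `end_incl` in the constructor is the last
#' calendar day on which the rate applies (matching how contracts state
#' "until January 31"), and the final period is open-ended (`NA`).
#'
#' @param start Date vector (or coercible), first day of each period.
#' @param end_incl Date vector, last day of each period inclusive; the
#'   final element must be `NA` (open-ended).
#' @param daily_rate_eur numeric, euro rate per device-day (cent-exact,
#'   non-negative).
#' @return a `tariff_schedule` data frame with columns `start`,
#'   `end` (exclusive, `NA` for the open-ended tail) and `rate_cents`.
#' @examples
#' study_tariff()   # the three-rate schedule used in the analysis
#' @export
tariff_schedule <- function(start, end_incl, daily_rate_eur) {
  start <- as.Date(start)
  end_incl <- as.Date(end_incl)
  if (length(start) < 1L ||
      length(end_incl) != length(start) ||
      length(daily_rate_eur) != length(start)) {
    stop("start, end_incl and daily_rate_eur must have equal length >= 1",
         call. = FALSE)
  }
  if (any(is.na(start))) stop("period start dates must not be NA", call. = FALSE)
  n <- length(start)
  if (!is.na(end_incl[n])) {
    stop("final tariff period must be open-ended (end_incl = NA)",
         call. = FALSE)
  }
  if (n > 1L && any(is.na(end_incl[-n]))) {
    stop("only the final tariff period may be open-ended", call. = FALSE)
  }
  rate <- money(daily_rate_eur)
  if (any(cents(rate) < 0)) stop("daily rates must be non-negative", call. = FALSE)
  end <- end_incl + 1L  # half-open exclusive bound
  if (n > 1L) {
    if (any(diff(as.numeric(start)) <= 0)) {
      stop("tariff periods must be in increasing date order", call. = FALSE)
    }
    gaps <- which(end[-n] != start[-1L])
    if (length(gaps)) {
      stop(sprintf(
        "tariff schedule not contiguous: period ending %s is not followed by a period starting %s",
        format(end_incl[gaps[1]]), format(end[gaps[1]])), call. = FALSE)
    }
  }
  if (any(!is.na(end) & end <= start)) {
    stop("each tariff period must span at least one day", call. = FALSE)
  }
  structure(
    data.frame(start = start, end = end, rate_cents = cents(rate)),
    class = c("tariff_schedule", "data.frame"))
}

#' @export
print.tariff_schedule <- function(x, ...) {
  cat("Tariff schedule (", nrow(x), " periods):\n", sep = "")
  for (i in seq_len(nrow(x))) {
    tail <- if (is.na(x$end[i])) "onwards" else paste("to", format(x$end[i] - 1L))
    cat(sprintf("  %s %s: %s per device-day\n", format(x$start[i]), tail,
                format(money_from_cents(x$rate_cents[i]))))
  }
  invisible(x)
}

#' Follow-up interval in whole days
#'
#' Half-open `[start, end)` span; a patient entering and leaving the same
#' day has zero billable days and is rejected.
#'
#' @param start entry date (inclusive).
#' @param end exit date (exclusive).
#' @return integer day count.
#' @export
interval_days <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  d <- as.integer(end - start)
  if (any(is.na(d)) || any(d < 1L)) {
    stop("follow-up interval must satisfy start < end", call. = FALSE)
  }
  d
}

#' Partition a follow-up interval across tariff periods
#'
#' Assigns every calendar day of `[start, end)` to the unique tariff
#' period containing it. Day counts always sum exactly to the interval
#' length (conservation), which is what makes the downstream accrual
#' auditable.
#'
#' @param start,end follow-up interval, half-open `[start, end)`.
#' @param schedule a [tariff_schedule()].
#' @return data frame with one row per overlapped period: `period`,
#'   `rate_eur`, `days`.
#' @export
split_days_by_period <- function(start, end, schedule) {
  stopifnot(inherits(schedule, "tariff_schedule"))
  start <- as.Date(start); end <- as.Date(end)
  interval_days(start, end)
  if (start < schedule$start[1L]) {
    stop(sprintf("interval start %s predates tariff schedule start %s",
                 format(start), format(schedule$start[1L])), call. = FALSE)
  }
  s <- as.numeric(start); e <- as.numeric(end)
  p_start <- as.numeric(schedule$start)
  p_end <- as.numeric(schedule$end)
  p_end[is.na(p_end)] <- Inf
  days <- pmax(0, pmin(e, p_end) - pmax(s, p_start))
  out <- data.frame(period = seq_len(nrow(schedule)),
                    rate_eur = schedule$rate_cents / 100,
                    days = as.integer(days))
  stopifnot(sum(out$days) == as.integer(end - start))  # conservation
  out[out$days > 0L, , drop = FALSE]
}

#' Rental cost of one follow-up interval under a tariff schedule
#'
#' @inheritParams split_days_by_period
#' @return scalar `money`: sum over periods of days x daily rate.
#' @export
rental_cost <- function(start, end, schedule) {
  sp <- split_days_by_period(start, end, schedule)
  money_from_cents(sum(sp$days * round(sp$rate_eur * 100)))
}

#' Outsourced-arm cost of a cohort
#'
#' What the external provider would have billed for every patient's
#' follow-up at the contracted per-device-day rates. An empty cohort
#' costs zero.
#'
#' @param cohort data frame with columns `patient_id`, `entry_date`,
#'   `end_date` (half-open follow-up) and optionally `status`.
#' @param schedule a [tariff_schedule()].
#' @return list with `total` (`money`) and `per_patient` (data frame of
#'   `patient_id`, `days`, `cost_eur`); per-patient accruals sum to the
#'   total by construction.
#' @export
outsourced_cost <- function(cohort, schedule) {
  if (is.null(cohort) || nrow(cohort) == 0L) {
    return(list(total = money(0),
                per_patient = data.frame(patient_id = character(),
                                         days = integer(),
                                         cost_eur = numeric())))
  }
  req <- c("patient_id", "entry_date", "end_date")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  per <- lapply(seq_len(nrow(cohort)), function(i) {
    cost <- rental_cost(cohort$entry_date[i], cohort$end_date[i], schedule)
    data.frame(patient_id = cohort$patient_id[i],
               days = interval_days(cohort$entry_date[i], cohort$end_date[i]),
               cost_eur = eur(cost))
  })
  per <- do.call(rbind, per)
  list(total = money_from_cents(sum(round(per$cost_eur * 100))),
       per_patient = per)
}
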