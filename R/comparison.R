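#' Head-to-head cost comparison of the two provision systems
#'
#' Bundles the two arm totals with the cohort structure so every headline
#' metric (saving, subgroup decomposition, cost per device-day) is
#' computed from one validated object. The subgroup savings, when
#' supplied, must decompose the total saving exactly in cents.
#'
#' @param internal_total scalar `money`, microcosted internalized spend.
#' @param outsourced_total scalar `money`, accrued (or contracted)
#'   outsourced spend over the same follow-up.
#' @param patient_days positive integer, total device-days of follow-up.
#' @param n_new,n_prevalent patient counts by status at entry
#'   (new = CPAP initiated at study entry; prevalent = already on CPAP).
#' @param subgroup_savings optional named `money` vector with elements
#'   `new` and `prevalent`; must sum to `outsourced_total - internal_total`.
#' @return a `cost_comparison` object.
#' @export
cost_comparison <- function(internal_total, outsourced_total, patient_days,
                            n_new, n_prevalent, subgroup_savings = NULL) {
  stopifnot(inherits(internal_total, "money"),
            inherits(outsourced_total, "money"))
  if (!is.numeric(patient_days) || patient_days <= 0 ||
      patient_days != round(patient_days)) {
    stop("patient_days must be a positive integer", call. = FALSE)
  }
  if (n_new < 0 || n_prevalent < 0 || n_new + n_prevalent < 1) {
    stop("cohort must contain at least one patient", call. = FALSE)
  }
  saving <- outsourced_total - internal_total
  if (!is.null(subgroup_savings)) {
    stopifnot(inherits(subgroup_savings, "money"))
    if (!all(c("new", "prevalent") %in% names(subgroup_savings))) {
      stop("subgroup_savings needs elements named 'new' and 'prevalent'",
           call. = FALSE)
    }
    tot <- sum(cents(subgroup_savings))
    if (tot != cents(saving)) {
      stop(sprintf(
        "subgroup savings (%s) do not decompose the total saving (%s)",
        format(money_from_cents(tot)), format(saving)), call. = FALSE)
    }
  }
  structure(list(internal_total = internal_total,
                 outsourced_total = outsourced_total,
                 patient_days = as.integer(patient_days),
                 n_new = as.integer(n_new),
                 n_prevalent = as.integer(n_prevalent),
                 subgroup_savings = subgroup_savings),
            class = "cost_comparison")
}

#' Direct saving of internalization
#'
#' Outsourced minus internalized total; negative if internalization
#' costs more.
#'
#' @param cmp a [cost_comparison()].
#' @return scalar `money`.
#' @export
direct_saving <- function(cmp) {
  stopifnot(inherits(cmp, "cost_comparison"))
  cmp$outsourced_total - cmp$internal_total
}

#' Cost per device-day
#'
#' The outsourced provider invoices per device and day, so both arms are
#' expressed on that unit for comparability. Rounding mode is explicit
#' because printed figures mix conventions.
#'
#' @param total scalar `money` arm total.
#' @param patient_days positive device-day denominator.
#' @param rounding `"half_up"` (default) or `"truncate"`.
#' @return list with `eur` (2-decimal figure), `exact_eur`, `rounding`.
#' @export
per_device_day <- function(total, patient_days,
                           rounding = c("half_up", "truncate")) {
  money_per_unit(total, patient_days, match.arg(rounding))
}

#' Average saving per patient within a status subgroup
#'
#' @param subgroup_saving scalar `money`.
#' @param n subgroup size, at least 1.
#' @param rounding `"truncate"` (default) or `"half_up"`.
#' @return list with `eur`, `exact_eur`, `rounding`.
#' @export
average_saving_per_patient <- function(subgroup_saving, n,
                                       rounding = c("truncate", "half_up")) {
  money_per_unit(subgroup_saving, n, match.arg(rounding))
}

#' Machine-readable comparison report
#'
#' Every euro figure appears both rounded (with its mode) and unrounded,
#' so downstream consumers can re-derive any printed number.
#'
#' @param cmp a [cost_comparison()].
#' @param device_day_rounding rounding mode for per-device-day figures.
#' @param per_patient_rounding rounding mode for per-patient averages.
#' @return nested list ready for JSON serialisation.
#' @export
comparison_report <- function(cmp, device_day_rounding = "half_up",
                              per_patient_rounding = "truncate") {
  stopifnot(inherits(cmp, "cost_comparison"))
  saving <- direct_saving(cmp)
  rep <- list(
    totals = list(
      internal_eur = eur(cmp$internal_total),
      outsourced_eur = eur(cmp$outsourced_total),
      direct_saving_eur = eur(saving)),
    cohort = list(
      patient_days = cmp$patient_days,
      n_new = cmp$n_new,
      n_prevalent = cmp$n_prevalent),
    per_device_day = list(
      internal = per_device_day(cmp$internal_total, cmp$patient_days,
                                device_day_rounding),
      outsourced = per_device_day(cmp$outsourced_total, cmp$patient_days,
                                  device_day_rounding)))
  if (!is.null(cmp$subgroup_savings)) {
    sg <- cmp$subgroup_savings
    rep$subgroups <- list(
      new = list(
        saving_eur = eur(sg["new"]),
        per_patient = average_saving_per_patient(sg["new"], cmp$n_new,
                                                 per_patient_rounding)),
      prevalent = list(
        saving_eur = eur(sg["prevalent"]),
        per_patient = average_saving_per_patient(sg["prevalent"],
                                                 cmp$n_prevalent,
                                                 per_patient_rounding)))
  }
  rep
}

#' @export
print.cost_comparison <- function(x, ...) {
  cat("Cost comparison (", x$n_new, " new + ", x$n_prevalent,
      " prevalent patients, ", format(x$patient_days, big.mark = ","),
      " patient-days)\n", sep = "")
  cat("  internalized: ", format(x$internal_total), "\n", sep = "")
  cat("  outsourced:   ", format(x$outsourced_total), "\n", sep = "")
  cat("  saving:       ", format(direct_saving(x)), "\n", sep = "")
  pdd_i <- per_device_day(x$internal_total, x$patient_days)
  pdd_o <- per_device_day(x$outsourced_total, x$patient_days)
  cat(sprintf("  per device-day: %.2f vs %.2f (half-up)\n",
              pdd_i$eur, pdd_o$eur))
  invisible(x)
}
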