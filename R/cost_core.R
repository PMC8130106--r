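#' Item catalogue for microcosting
#'
#' The internalized service is costed bottom-up: every device and
#' accessory actually handed to a patient is priced at its retail unit
#' cost (VAT included) and charged in full at acquisition — no
#' annualization of the CPAP device over its 5-year useful life, so the
#' figures reflect the cash actually spent in the period.
#'
#' @param name character, unique item labels.
#' @param unit_cost_eur numeric, positive cent-exact euro unit prices.
#' @return an `item_catalogue` data frame with `name`, `unit_cost_cents`.
#' @examples
#' study_catalogue()
#' @export
item_catalogue <- function(name, unit_cost_eur) {
  if (length(name) != length(unit_cost_eur)) {
    stop("name and unit_cost_eur must have equal length", call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("item names must be unique within a catalogue: duplicated ",
         name[duplicated(name)][1], call. = FALSE)
  }
  uc <- money(unit_cost_eur)
  if (any(cents(uc) <= 0)) stop("unit costs must be positive", call. = FALSE)
  structure(data.frame(name = as.character(name),
                       unit_cost_cents = cents(uc),
                       stringsAsFactors = FALSE),
            class = c("item_catalogue", "data.frame"))
}

#' Total consumables and equipment spend with per-item breakdown
#'
#' Sums quantity x unit cost over a usage ledger. The breakdown is
#' returned so the per-item subtotals can be audited against the total
#' (they sum to it exactly, in cents).
#'
#' @param catalogue an [item_catalogue()].
#' @param usage data frame with columns `item` and `quantity`
#'   (positive integers); `patient_id` and `date` columns, if present,
#'   are carried through validation but not needed for the total.
#' @return list with `total` (`money`) and `by_item` (data frame of
#'   `name`, `unit_cost_eur`, `quantity`, `subtotal_eur`).
#' @export
consumables_total <- function(catalogue, usage) {
  stopifnot(inherits(catalogue, "item_catalogue"))
  if (is.null(usage) || nrow(usage) == 0L) {
    return(list(total = money(0),
                by_item = data.frame(name = character(),
                                     unit_cost_eur = numeric(),
                                     quantity = integer(),
                                     subtotal_eur = numeric())))
  }
  if (!all(c("item", "quantity") %in% names(usage))) {
    stop("usage ledger needs `item` and `quantity` columns", call. = FALSE)
  }
  unknown <- setdiff(unique(usage$item), catalogue$name)
  if (length(unknown)) {
    stop("usage references items not in the catalogue: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  q <- usage$quantity
  if (any(is.na(q)) || any(q < 1) || any(q != round(q))) {
    stop("quantities must be positive integers", call. = FALSE)
  }
  agg <- stats::aggregate(quantity ~ item, data = usage, FUN = sum)
  idx <- match(agg$item, catalogue$name)
  sub_cents <- catalogue$unit_cost_cents[idx] * agg$quantity
  by_item <- data.frame(name = agg$item,
                        unit_cost_eur = catalogue$unit_cost_cents[idx] / 100,
                        quantity = as.integer(agg$quantity),
                        subtotal_eur = sub_cents / 100,
                        stringsAsFactors = FALSE)
  # present in catalogue order
  by_item <- by_item[order(match(by_item$name, catalogue$name)), , drop = FALSE]
  rownames(by_item) <- NULL
  list(total = money_from_cents(sum(sub_cents)), by_item = by_item)
}

#' Nursing follow-up cost
#'
#' Therapy follow-up in the internalized arm is done by hospital nurses;
#' their time is imputed as whole workdays at the collective-agreement
#' daily wage (default € 153.51). The workday count is an explicit
#' assumption, not a constant.
#'
#' @param workdays non-negative integer number of full nursing days.
#' @param daily_wage `money`, wage per nursing workday.
#' @return scalar `money`.
#' @export
nursing_cost <- function(workdays, daily_wage = money(153.51)) {
  stopifnot(inherits(daily_wage, "money"), length(daily_wage) == 1L)
  if (!is.numeric(workdays) || length(workdays) != 1L || workdays < 0 ||
      workdays != round(workdays)) {
    stop("workdays must be a non-negative integer", call. = FALSE)
  }
  daily_wage * workdays
}

#' Total cost of the internalized service
#'
#' Consumables-and-equipment spend plus imputed nursing time. Structure
#' costs (space, administration) and supplies (electricity, water) are
#' outside the costing perimeter.
#'
#' @param consumables scalar `money`, output of [consumables_total()].
#' @param nursing scalar `money`, output of [nursing_cost()].
#' @return scalar `money`.
#' @export
internal_total <- function(consumables, nursing) {
  stopifnot(inherits(consumables, "money"), inherits(nursing, "money"))
  consumables + nursing
}

#' Validate a usage ledger against a cohort's follow-up intervals
#'
#' Every replacement event must fall inside the owning patient's
#' half-open follow-up span `[entry, end)`.
#'
#' @param usage data frame with `patient_id`, `item`, `date`, `quantity`.
#' @param cohort data frame with `patient_id`, `entry_date`, `end_date`.
#' @return invisibly `TRUE`; errors describe the first violation.
#' @export
validate_usage <- function(usage, cohort) {
  if (nrow(usage) == 0L) return(invisible(TRUE))
  idx <- match(usage$patient_id, cohort$patient_id)
  if (anyNA(idx)) {
    stop("usage event for unknown patient ",
         usage$patient_id[which(is.na(idx))[1]], call. = FALSE)
  }
  d <- as.Date(usage$date)
  lo <- as.Date(cohort$entry_date)[idx]
  hi <- as.Date(cohort$end_date)[idx]
  bad <- which(d < lo | d >= hi)
  if (length(bad)) {
    stop(sprintf("usage event on %s outside follow-up [%s, %s) of patient %s",
                 format(d[bad[1]]), format(lo[bad[1]]), format(hi[bad[1]]),
                 usage$patient_id[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}
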