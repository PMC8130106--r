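#' Budget-impact projection specification
#'
#' Multi-year projection of the traditional (outsourced) versus
#' alternative (internalized) cost of serving a health area. The
#' traditional arm compounds a base-year cost at a constant growth rate;
#' the alternative arm either takes supplied per-year costs (e.g. a
#' published table) or is generated from a recurrent
#' consumables-plus-personnel cost and a full device repurchase in the
#' investment year and again every device lifetime.
#'
#' @param base_year first projected calendar year.
#' @param horizon_years number of projected years (>= 1; 0 gives an
#'   empty projection from [project()]).
#' @param traditional_base_cost scalar `money`, traditional-arm cost in
#'   the base year.
#' @param traditional_growth_rate per-year growth fraction (> -1).
#' @param alternative_year_costs optional `money` vector of length
#'   `horizon_years`: the alternative-arm yearly costs, used verbatim.
#' @param alternative_recurrent_cost scalar `money`: base-year
#'   consumables + personnel cost of the alternative arm (used when
#'   per-year costs are not supplied).
#' @param alternative_growth_rate per-year growth of the recurrent part.
#' @param device_investment_cost scalar `money`: full device purchase
#'   cost, charged in the investment year and every
#'   `device_lifetime_years` thereafter (no annualization).
#' @param device_lifetime_years useful life of a device, default 5.
#' @param population assigned population of the health area (metadata).
#' @return a `projection_spec` object.
#' @export
projection_spec <- function(base_year, horizon_years,
                            traditional_base_cost, traditional_growth_rate,
                            alternative_year_costs = NULL,
                            alternative_recurrent_cost = NULL,
                            alternative_growth_rate = 0,
                            device_investment_cost = NULL,
                            device_lifetime_years = 5,
                            population = NA_integer_) {
  stopifnot(inherits(traditional_base_cost, "money"))
  if (horizon_years < 0 || horizon_years != round(horizon_years)) {
    stop("horizon_years must be a non-negative integer", call. = FALSE)
  }
  if (traditional_growth_rate <= -1) {
    stop("growth rate must exceed -1", call. = FALSE)
  }
  if (device_lifetime_years < 1) {
    stop("device_lifetime_years must be >= 1", call. = FALSE)
  }
  if (is.null(alternative_year_costs)) {
    if (is.null(alternative_recurrent_cost) || is.null(device_investment_cost)) {
      stop(paste("supply either alternative_year_costs or both",
                 "alternative_recurrent_cost and device_investment_cost"),
           call. = FALSE)
    }
    stopifnot(inherits(alternative_recurrent_cost, "money"),
              inherits(device_investment_cost, "money"))
  } else {
    stopifnot(inherits(alternative_year_costs, "money"))
    if (length(alternative_year_costs) != horizon_years) {
      stop("alternative_year_costs must have one value per projected year",
           call. = FALSE)
    }
  }
  structure(list(base_year = as.integer(base_year),
                 horizon_years = as.integer(horizon_years),
                 traditional_base_cost = traditional_base_cost,
                 traditional_growth_rate = traditional_growth_rate,
                 alternative_year_costs = alternative_year_costs,
                 alternative_recurrent_cost = alternative_recurrent_cost,
                 alternative_growth_rate = alternative_growth_rate,
                 device_investment_cost = device_investment_cost,
                 device_lifetime_years = as.integer(device_lifetime_years),
                 population = population),
            class = "projection_spec")
}

row_metrics <- function(trad_cents, alt_cents) {
  diff_cents <- trad_cents - alt_cents
  pct <- ifelse(trad_cents == 0, NA_real_,
                round_half_up(100 * diff_cents / trad_cents, 2))
  list(diff_cents = diff_cents, pct = pct)
}

#' Run a budget-impact projection
#'
#' @param spec a [projection_spec()].
#' @return a `projection_table`: data frame with one row per year and
#'   columns `year`, `traditional_eur`, `alternative_eur`,
#'   `difference_eur`, `difference_pct` (half-up, 2 decimals). Row
#'   identities `difference = traditional - alternative` hold in cents.
#' @export
project <- function(spec) {
  stopifnot(inherits(spec, "projection_spec"))
  h <- spec$horizon_years
  if (h == 0L) {
    return(projection_table(integer(), numeric(), numeric()))
  }
  yrs <- spec$base_year + seq_len(h) - 1L
  g <- spec$traditional_growth_rate
  trad_cents <- round(cents(spec$traditional_base_cost) * (1 + g)^(seq_len(h) - 1))
  if (!is.null(spec$alternative_year_costs)) {
    alt_cents <- cents(spec$alternative_year_costs)
  } else {
    ga <- spec$alternative_growth_rate
    rec <- round(cents(spec$alternative_recurrent_cost) * (1 + ga)^(seq_len(h) - 1))
    buy <- (seq_len(h) - 1L) %% spec$device_lifetime_years == 0L
    alt_cents <- rec + buy * cents(spec$device_investment_cost)
  }
  projection_table(yrs, trad_cents / 100, alt_cents / 100)
}

#' Assemble (or re-derive) a projection table from yearly costs
#'
#' Differences and percentages are always recomputed from the cost
#' columns; supplied values, if any, are checked and discrepancies
#' beyond € 0.01 / 0.01 pp flagged in the `flags` attribute rather than
#' silently replaced.
#'
#' @param year integer years.
#' @param traditional_eur,alternative_eur cent-exact euro costs.
#' @param difference_eur,difference_pct optional supplied columns to
#'   verify against.
#' @return a `projection_table` data frame.
#' @export
projection_table <- function(year, traditional_eur, alternative_eur,
                             difference_eur = NULL, difference_pct = NULL) {
  trad <- money(traditional_eur); alt <- money(alternative_eur)
  m <- row_metrics(cents(trad), cents(alt))
  flags <- character(0)
  if (!is.null(difference_eur)) {
    bad <- which(abs(m$diff_cents / 100 - difference_eur) > 0.01 + 1e-9)
    if (length(bad)) {
      flags <- c(flags, sprintf(
        "year %s: supplied difference %.2f vs recomputed %.2f",
        year[bad], difference_eur[bad], m$diff_cents[bad] / 100))
    }
  }
  if (!is.null(difference_pct)) {
    bad <- which(abs(m$pct - difference_pct) > 0.01 + 1e-9)
    if (length(bad)) {
      flags <- c(flags, sprintf(
        "year %s: supplied difference_pct %.2f vs recomputed %.2f",
        year[bad], difference_pct[bad], m$pct[bad]))
    }
  }
  structure(data.frame(year = as.integer(year),
                       traditional_eur = cents(trad) / 100,
                       alternative_eur = cents(alt) / 100,
                       difference_eur = m$diff_cents / 100,
                       difference_pct = m$pct),
            flags = flags,
            class = c("projection_table", "data.frame"))
}

#' Column totals and arithmetic check of a projection table
#'
#' Totals are column sums, exact in cents; the total percentage is
#' 100 x (sum of differences) / (sum of traditional costs), rounded
#' half-up to 2 decimals.
#'
#' @param rows a `projection_table` with at least one row.
#' @return list with `total_traditional`, `total_alternative`,
#'   `total_difference` (each `money`), `total_difference_pct`, and
#'   `flags` (character vector of per-row discrepancies, if any).
#' @export
table_consistency <- function(rows) {
  stopifnot(inherits(rows, "projection_table"))
  if (nrow(rows) < 1L) stop("projection table has no rows", call. = FALSE)
  tt <- sum(round(rows$traditional_eur * 100))
  ta <- sum(round(rows$alternative_eur * 100))
  td <- sum(round(rows$difference_eur * 100))
  stopifnot(td == tt - ta)
  list(total_traditional = money_from_cents(tt),
       total_alternative = money_from_cents(ta),
       total_difference = money_from_cents(td),
       total_difference_pct = round_half_up(100 * td / tt, 2),
       flags = attr(rows, "flags") %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Device-price sensitivity scenario
#'
#' Scales the device-attributable component of every alternative-arm
#' year by a price multiplier, leaving non-device components untouched,
#' and recomputes the rows. Because the alternative-arm total is affine
#' in the multiplier, savings are non-increasing in it and the base case
#' (multiplier 1) reproduces the input exactly.
#'
#' @param rows a `projection_table` (the base projection).
#' @param multiplier positive device-price factor; 1.0 is the base case.
#' @param device_share_eur per-year device-attributable euro cost within
#'   the alternative arm: a single number (recycled) or one per row.
#' @param label optional scenario label stored as an attribute.
#' @return a new `projection_table`.
#' @export
apply_scenario <- function(rows, multiplier, device_share_eur, label = NULL) {
  stopifnot(inherits(rows, "projection_table"))
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0) {
    stop("device price multiplier must be a positive number", call. = FALSE)
  }
  share_cents <- round(rep_len(device_share_eur, nrow(rows)) * 100)
  if (any(share_cents < 0) ||
      any(share_cents > round(rows$alternative_eur * 100))) {
    stop("device share must lie within [0, alternative cost] each year",
         call. = FALSE)
  }
  alt_cents <- round(rows$alternative_eur * 100) +
    round((multiplier - 1) * share_cents)
  out <- projection_table(rows$year, rows$traditional_eur, alt_cents / 100)
  attr(out, "scenario") <- list(label = label %||% sprintf("x%.2f", multiplier),
                                multiplier = multiplier)
  out
}

#' Run a suite of device-price scenarios and summarise
#'
#' @param rows base `projection_table`.
#' @param multipliers numeric vector of price factors (default base,
#'   +25%, +50%).
#' @param device_fraction fraction of each alternative-arm year that is
#'   device-attributable (used to derive the per-year device share).
#' @return data frame with one row per scenario: `multiplier`,
#'   `total_alternative_eur`, `total_difference_eur`,
#'   `total_difference_pct`.
#' @export
scenario_suite <- function(rows, multipliers = c(1, 1.25, 1.5),
                           device_fraction = 0.4667) {
  stopifnot(device_fraction >= 0, device_fraction <= 1)
  share <- round(rows$alternative_eur * device_fraction * 100) / 100
  out <- lapply(multipliers, function(m) {
    sc <- apply_scenario(rows, m, share)
    tc <- table_consistency(sc)
    data.frame(multiplier = m,
               total_alternative_eur = eur(tc$total_alternative),
               total_difference_eur = eur(tc$total_difference),
               total_difference_pct = tc$total_difference_pct)
  })
  do.call(rbind, out)
}

#' @export
print.projection_table <- function(x, ...) {
  cat("Budget-impact projection (", nrow(x), " years)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  fl <- attr(x, "flags")
  if (length(fl)) cat("flags:\n ", paste(fl, collapse = "\n  "), "\n")
  invisible(x)
}
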