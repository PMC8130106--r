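#' Exact euro amounts held in integer cents
#'
#' Currency is represented as an integer number of cents so that every
#' accrual and sum in the costing pipeline is exact; floating point only
#' ever appears when an explicit division or rounding step asks for it.
#' Negative amounts are permitted (cost differences can be negative).
#'
#' @param eur numeric vector of euro amounts; must be cent-exact
#'   (an integer number of cents to within 1e-6 cents).
#' @return a `money` vector.
#' @examples
#' money(151.68) * 21            # cent-exact product
#' sum(money(c(5904.05, 921.06)))
#' @export
money <- function(eur) {
  if (!is.numeric(eur)) stop("`eur` must be numeric", call. = FALSE)
  cents <- eur * 100
  r <- round(cents)
  off <- abs(cents - r) > 1e-6
  if (any(off, na.rm = TRUE)) {
    stop(sprintf("amount %.6f is not cent-exact", eur[which(off)[1]]),
         call. = FALSE)
  }
  money_from_cents(r)
}

#' Construct money from integer cents
#' @param cents numeric vector of integer cent values.
#' @return a `money` vector.
#' @export
money_from_cents <- function(cents) {
  if (!is.numeric(cents)) stop("`cents` must be numeric", call. = FALSE)
  r <- round(cents)
  if (any(abs(cents - r) > 1e-6, na.rm = TRUE)) {
    stop("cents must be whole numbers", call. = FALSE)
  }
  structure(as.numeric(r), class = "money")
}

#' Integer cents of a money vector
#' @param m a `money` vector.
#' @return numeric vector of cents.
#' @export
cents <- function(m) {
  stopifnot(inherits(m, "money"))
  unclass(m)
}

#' Euro value of a money vector
#' @param m a `money` vector.
#' @return numeric euros (cents / 100).
#' @export
eur <- function(m) {
  stopifnot(inherits(m, "money"))
  unclass(m) / 100
}

#' @export
format.money <- function(x, big.mark = ",", ...) {
  paste0("€ ", formatC(unclass(x) / 100, format = "f", digits = 2,
                            big.mark = big.mark))
}

#' @export
print.money <- function(x, ...) {
  print(format(x), quote = FALSE)
  invisible(x)
}

#' @export
c.money <- function(...) {
  parts <- lapply(list(...), function(p) {
    if (!inherits(p, "money")) stop("can only combine money with money",
                                    call. = FALSE)
    unclass(p)
  })
  money_from_cents(unlist(parts))
}

#' @export
`[.money` <- function(x, i) money_from_cents(unclass(x)[i])

#' @export
Ops.money <- function(e1, e2) {
  if (missing(e2)) {  # unary + / -
    if (.Generic %in% c("+", "-")) {
      return(money_from_cents(get(.Generic)(unclass(e1))))
    }
    stop(sprintf("unary %s not defined for money", .Generic), call. = FALSE)
  }
  m1 <- inherits(e1, "money"); m2 <- inherits(e2, "money")
  if (.Generic %in% c("+", "-")) {
    if (!(m1 && m2)) {
      stop(sprintf("%s requires two money operands", .Generic), call. = FALSE)
    }
    return(money_from_cents(get(.Generic)(unclass(e1), unclass(e2))))
  }
  if (.Generic == "*") {
    if (m1 && m2) stop("cannot multiply money by money", call. = FALSE)
    cts <- if (m1) unclass(e1) * e2 else e1 * unclass(e2)
    return(money_from_cents(cts))  # errors unless product is cent-exact
  }
  if (.Generic == "/") {
    if (m1 && m2) return(unclass(e1) / unclass(e2))  # dimensionless ratio
    stop("division of money by a count goes through money_per_unit()",
         call. = FALSE)
  }
  if (.Generic %in% c("==", "!=", "<", "<=", ">", ">=")) {
    if (!(m1 && m2)) stop("comparison requires two money operands",
                          call. = FALSE)
    return(get(.Generic)(unclass(e1), unclass(e2)))
  }
  stop(sprintf("operation %s not defined for money", .Generic), call. = FALSE)
}

#' @export
Summary.money <- function(..., na.rm = FALSE) {
  if (!.Generic %in% c("sum", "min", "max", "range")) {
    stop(sprintf("%s not defined for money", .Generic), call. = FALSE)
  }
  cts <- unlist(lapply(list(...), function(p) {
    if (!inherits(p, "money")) stop("money summary over non-money operand",
                                    call. = FALSE)
    unclass(p)
  }))
  money_from_cents(get(.Generic)(cts, na.rm = na.rm))
}

# ---- explicit rounding modes -------------------------------------------

#' Round half away from zero ("commercial" rounding)
#'
#' `round()` in R rounds half to even; printed financial figures here use
#' half-up, so the mode is explicit. A magnitude-scaled tolerance absorbs
#' binary representation error at the .5 boundary.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  y <- abs(x) * p
  tol <- pmax(1e-9, y * 1e-12)
  sign(x) * floor(y + 0.5 + tol) / p
}

#' Truncate toward zero at a number of decimals
#' @inheritParams round_half_up
#' @return truncated numeric.
#' @export
round_truncate <- function(x, digits = 0) {
  p <- 10^digits
  y <- abs(x) * p
  tol <- pmax(1e-9, y * 1e-12)
  sign(x) * floor(y + tol) / p
}

#' Divide a money total by a count, with an explicit rounding mode
#'
#' Returns both the unrounded quotient and the 2-decimal euro figure so
#' downstream sums never accumulate rounding error.
#'
#' @param total a scalar `money` amount.
#' @param n positive count (e.g. patient-days or patients).
#' @param rounding `"half_up"` or `"truncate"`.
#' @return list with `eur` (rounded to 2 decimals), `exact_eur`
#'   (unrounded quotient) and `rounding`.
#' @export
money_per_unit <- function(total, n, rounding = c("half_up", "truncate")) {
  stopifnot(inherits(total, "money"), length(total) == 1L)
  rounding <- match.arg(rounding)
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  exact_eur <- cents(total) / n / 100
  rounded <- switch(rounding,
                    half_up  = round_half_up(exact_eur, 2),
                    truncate = round_truncate(exact_eur, 2))
  list(eur = rounded, exact_eur = exact_eur, rounding = rounding)
}
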