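#' Contingency table of survey responses by provision system
#'
#' Columns are the systems being compared, rows the response categories.
#' Column totals may differ: patients new to CPAP answered only for the
#' internalized system, so that column carries the full cohort while the
#' external column carries only patients with prior outsourced
#' experience.
#'
#' @param counts non-negative integer matrix (responses x systems).
#' @param row_labels,col_labels optional dimension labels.
#' @return a `contingency_table` matrix.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", class(counts)))
}

#' Pearson chi-square test on a response-by-system table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1).
#' All-zero response rows are dropped (with a message) before testing:
#' they carry no information and would make expected counts degenerate.
#' Expected cells below 5 trigger a warning condition because the
#' classic chi-square validity rule is violated — surfaced, not fixed.
#'
#' Because sparse multi-category tables can push an exact-looking effect
#' above conventional p-value landmarks, `collapse = "binary"` merges
#' the table to top-category versus rest (a 2 x c table) before testing;
#' both variants are legitimate readings of a 4-level satisfaction item
#' and both are exposed.
#'
#' @param tab a [contingency_table()] (or plain matrix) with >= 2 rows
#'   and >= 2 columns after zero-row removal.
#' @param collapse `"none"` (default) tests the full table;
#'   `"binary"` collapses to first row vs all remaining rows.
#' @return list with `statistic`, `df`, `p_value`, `expected`,
#'   `dropped_rows`, `small_cells` (number of expected counts < 5) and
#'   `collapse`.
#' @export
chi_square_test <- function(tab, collapse = c("none", "binary")) {
  collapse <- match.arg(collapse)
  counts <- unclass(as.matrix(tab))
  if (collapse == "binary") {
    if (nrow(counts) < 2L) stop("cannot collapse a table with < 2 rows",
                                call. = FALSE)
    top <- counts[1L, , drop = FALSE]
    rest <- colSums(counts[-1L, , drop = FALSE])
    counts <- rbind(top, rest)
    rownames(counts) <- c(rownames(tab)[1L] %||% "top", "rest")
  }
  zero <- rowSums(counts) == 0
  dropped <- rownames(counts)[zero] %||% which(zero)
  if (any(zero)) {
    message("dropping all-zero response rows: ",
            paste(dropped, collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L ||
      any(colSums(counts) == 0)) {
    stop("chi-square test inapplicable: fewer than 2 non-degenerate rows/columns",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  small <- sum(ht$expected < 5)
  if (small > 0) {
    warning(sprintf("%d of %d expected counts are below 5; chi-square approximation is questionable",
                    small, length(ht$expected)), call. = FALSE)
  }
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       expected = ht$expected,
       dropped_rows = if (any(zero)) dropped else character(0),
       small_cells = small,
       collapse = collapse)
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided exact p-value under the hypergeometric null (all tables
#' with the observed margins, summing probabilities no larger than the
#' observed table's).
#'
#' @param tab a 2 x 2 [contingency_table()] or matrix.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_test <- function(tab) {
  counts <- unclass(as.matrix(tab))
  if (!all(dim(counts) == c(2L, 2L))) {
    stop("fisher_exact_test supports 2 x 2 tables only", call. = FALSE)
  }
  # fisher.test can overshoot 1 by a rounding ulp; the p-value is capped
  min(stats::fisher.test(counts)$p.value, 1)
}

#' Preference percentages among eligible respondents
#'
#' Which system do patients say serves them better? The denominator is
#' the respondents eligible to compare (those with prior outsourced
#' experience), and percentages are rounded half-up to one decimal.
#'
#' @param counts named non-negative integer vector of option counts.
#' @return data frame with `option`, `count`, `pct`; percentages sum to
#'   100 up to 0.1 of rounding.
#' @export
preference_summary <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector of options", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("no eligible respondents (zero denominator)", call. = FALSE)
  data.frame(option = names(counts),
             count = as.integer(counts),
             pct = round_half_up(100 * counts / n, 1),
             row.names = NULL,
             stringsAsFactors = FALSE)
}
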