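test_that("contingency tables validate counts and load from the fixture", {
  expect_error(contingency_table(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  sat <- study_satisfaction_table()
  expect_equal(dim(sat), c(4L, 2L))
  expect_equal(colSums(sat), c(internalized = 21L, external = 17L))
})

test_that("chi-square matches the closed-form 2x2 statistic", {
  set.seed(31)
  for (i in 1:40) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2)
    res <- suppressWarnings(chi_square_test(m))
    expect_equal(res$statistic, chisq_2x2_stat(m), tolerance = 1e-12)
    expect_equal(res$df, 1)
    expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))
  }
})

test_that("chi-square is permutation invariant and zero iff observed = expected", {
  m <- matrix(c(15, 6, 2, 12), 2)
  a <- suppressWarnings(chi_square_test(m))
  b <- suppressWarnings(chi_square_test(m[2:1, 2:1]))
  expect_equal(a$statistic, b$statistic)
  # identical columns: observed equals expected, statistic 0, p 1
  flat <- suppressWarnings(chi_square_test(matrix(c(5, 7, 5, 7), 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("degenerate tables error and zero rows are dropped with a note", {
  expect_error(suppressMessages(chi_square_test(matrix(c(3, 0, 4, 0), 2))),
               "inapplicable")
  qual <- survey_question_table(study_survey(), "quality")
  expect_message(res <- suppressWarnings(chi_square_test(qual)), "bad")
  expect_equal(res$df, 2)            # 4 rows minus the all-zero "bad" row
  expect_lt(res$p_value, 0.001)
  expect_gt(res$small_cells, 0)      # small expected counts are surfaced
})

test_that("satisfaction counts: full-table and binary-collapsed variants", {
  sat <- study_satisfaction_table()
  full <- suppressWarnings(suppressMessages(chi_square_test(sat)))
  expect_equal(full$df, 3)
  expect_lt(full$p_value, 0.01)
  bin <- suppressWarnings(chi_square_test(sat, collapse = "binary"))
  expect_equal(bin$df, 1)
  expect_lt(bin$p_value, 0.001)
})

test_that("Fisher exact equals hypergeometric enumeration on small tables", {
  # sweep every 2x2 table with total at most 12 and non-degenerate
  # margins (the exhaustive n <= 20 sweep runs in the acceptance suite)
  checked <- 0L; worst <- 0; in_range <- TRUE
  for (a in 0:12) for (b in 0:(12 - a)) for (cc in 0:(12 - a - b)) {
    for (d in 0:(12 - a - b - cc)) {
      m <- matrix(c(a, cc, b, d), 2)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      p <- fisher_exact_test(m)
      in_range <- in_range && p > 0 && p <= 1
      worst <- max(worst, abs(p - fisher_enum_p(m)))
      checked <- checked + 1L
    }
  }
  expect_true(in_range)
  expect_lt(worst, 1e-10)
  expect_gt(checked, 500)
})

test_that("Fisher handles the anti-diagonal and identical-row cases", {
  expect_equal(fisher_exact_test(matrix(c(0, 5, 5, 0), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_test(matrix(c(4, 4, 6, 6), 2)), 1)
  expect_error(fisher_exact_test(matrix(1:6, 2)), "2 x 2")
})

test_that("preference percentages round half-up to one decimal and sum to ~100", {
  pref <- preference_summary(c(internalized_system = 12, both_equally = 5,
                               external_company = 0))
  expect_equal(pref$pct[pref$option == "internalized_system"], 70.6)
  expect_equal(pref$pct[pref$option == "both_equally"], 29.4)
  expect_equal(pref$pct[pref$option == "external_company"], 0)
  expect_lte(abs(sum(pref$pct) - 100), 0.1)
  expect_equal(preference_summary(c(only = 9))$pct, 100)
  expect_equal(preference_summary(c(a = 1, b = 2))$pct, c(33.3, 66.7))
  expect_error(preference_summary(c(a = 0, b = 0)), "zero denominator")
})
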