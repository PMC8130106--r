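test_that("identical seed and config give identical cohorts", {
  cfg <- cohort_config(seed = 99L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$usage, b$usage)
  expect_identical(a$survey, b$survey)
  c <- generate_cohort(cohort_config(seed = 100L))
  expect_false(identical(a$usage, c$usage))
  # generation does not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(generate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("config validation rejects impossible windows and rates", {
  expect_error(cohort_config(recruitment_start = "2014-01-01",
                             recruitment_end = "2013-10-01"),
               "start < end")
  expect_error(cohort_config(follow_up_end = "2013-11-01"),
               "after the recruitment window")
  expect_error(cohort_config(dropout_rate = -0.1), ">= 0")
  expect_error(cohort_config(replacement_rates = c(nasal_mask = -1)),
               "non-negative")
})

test_that("an empty cohort flows through the pipeline at zero cost", {
  empty <- generate_cohort(cohort_config(n_new = 0, n_prevalent = 0,
                                         replacement_rates = c(nasal_mask = 1)))
  expect_equal(nrow(empty$patients), 0L)
  expect_equal(cents(outsourced_cost(empty$patients, study_tariff())$total), 0)
  expect_equal(cents(consumables_total(study_catalogue(), empty$usage)$total), 0)
})

test_that("default cohorts land near the study's patient-day total", {
  # expectation from window/endpoint arithmetic, then realized draws
  cfg <- cohort_config()
  expect_equal(expected_patient_years(cfg) * 365.25, 23046,
               tolerance = 0.05)
  for (seed in 1:10) {
    coh <- generate_cohort(cohort_config(seed = seed))
    days <- sum(as.integer(coh$patients$end_date - coh$patients$entry_date))
    expect_equal(days, 23046, tolerance = 0.05)
    expect_equal(table(coh$patients$status)[["new"]], 4)
    expect_equal(table(coh$patients$status)[["prevalent"]], 17)
  }
})

test_that("all generated events respect the follow-up intervals", {
  for (seed in c(3, 17)) {
    coh <- generate_cohort(cohort_config(seed = seed))
    expect_true(validate_usage(coh$usage, coh$patients))
    # one device issued at entry per patient
    cpap <- coh$usage[coh$usage$item == "CPAP", ]
    expect_equal(nrow(cpap), nrow(coh$patients))
    expect_equal(as.Date(cpap$date[order(cpap$patient_id)]),
                 coh$patients$entry_date[order(coh$patients$patient_id)])
  }
  # dropout shortens but never inverts follow-up
  dr <- generate_cohort(cohort_config(dropout_rate = 0.5, seed = 8))
  expect_true(all(dr$patients$end_date > dr$patients$entry_date))
  expect_true(all(dr$patients$end_date <= as.Date("2016-11-01")))
  expect_true(validate_usage(dr$usage, dr$patients))
})

test_that("calibration sets rates to target / expected patient-years", {
  cfg <- calibrate_to_table1(cohort_config())
  py <- expected_patient_years(cfg)
  expect_equal(cfg$replacement_rates[["nasal_mask"]], 45 / py)
  expect_equal(45 / py, 0.714, tolerance = 0.02)
  expect_false("CPAP" %in% names(cfg$replacement_rates))
  # a zero target means a zero rate and no events ever
  z <- cohort_config(replacement_rates = c(nasal_mask = 0), seed = 4)
  expect_equal(sum(generate_cohort(z)$usage$item == "nasal_mask"), 0)
  # degenerate cohort cannot be calibrated
  expect_error(calibrate_to_table1(cohort_config(n_new = 0, n_prevalent = 0)),
               "zero expected patient-years")
})

test_that("replacement counts satisfy a law-of-large-numbers check", {
  # mean simulated count over many seeds within 3 SE of rate x patient-years
  counts <- vapply(1:60, function(s) {
    coh <- generate_cohort(cohort_config(
      seed = s, replacement_rates = c(nasal_mask = 0.714)))
    sum(coh$usage$item == "nasal_mask")
  }, numeric(1))
  target <- 0.714 * expected_patient_years(cohort_config())
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - target), 3 * se)
})

test_that("synthetic cohorts close the full costing pipeline", {
  coh <- generate_cohort(cohort_config(seed = 12))
  oc <- outsourced_cost(coh$patients, study_tariff())
  cons <- consumables_total(study_catalogue(), coh$usage)
  internal <- internal_total(cons$total, nursing_cost(6))
  days <- sum(as.integer(coh$patients$end_date - coh$patients$entry_date))
  cmp <- cost_comparison(internal, oc$total, days,
                         sum(coh$patients$status == "new"),
                         sum(coh$patients$status == "prevalent"))
  rep <- comparison_report(cmp)
  expect_equal(rep$totals$direct_saving_eur,
               eur(oc$total) - eur(internal))
  expect_gt(rep$per_device_day$outsourced$exact_eur, 0.64)  # floor: rate 3
  sat <- contingency_table(cbind(internalized = coh$survey$internalized,
                                 external = coh$survey$external))
  expect_equal(colSums(sat), c(internalized = 21L, external = 17L))
})
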