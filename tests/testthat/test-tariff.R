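test_that("schedule constructor enforces contiguity and open end", {
  expect_s3_class(study_tariff(), "tariff_schedule")
  expect_error(
    tariff_schedule(c("2013-01-01", "2014-02-02"), c("2014-01-31", NA),
                    c(1.10, 0.86)),
    "not contiguous")
  expect_error(
    tariff_schedule("2013-01-01", "2014-01-31", 1.10),
    "open-ended")
  expect_error(
    tariff_schedule(c("2013-01-01", "2014-02-01"), c("2014-01-31", NA),
                    c(1.10, -0.5)),
    "non-negative")
})

test_that("an interval inside one period accrues at that single rate", {
  sched <- study_tariff()
  sp <- split_days_by_period("2014-07-07", "2014-07-17", sched)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$days, 10L)
  expect_equal(sp$rate_eur, 0.65)
  expect_equal(eur(rental_cost("2014-07-07", "2014-07-17", sched)), 6.50)
})

test_that("the rate-1/rate-2 boundary keeps 31 January on rate 1", {
  sched <- study_tariff()
  sp <- split_days_by_period("2014-01-30", "2014-02-03", sched)
  expect_equal(sp$days, c(2L, 2L))       # Jan 30-31 at 1.10, Feb 1-2 at 0.86
  expect_equal(sp$rate_eur, c(1.10, 0.86))
  expect_equal(eur(rental_cost("2014-01-30", "2014-02-03", sched)), 3.92)
  # oracle agreement on the boundary-crossing interval
  expect_equal(cents(rental_cost("2014-01-30", "2014-02-03", sched)),
               day_loop_cost_cents("2014-01-30", "2014-02-03", sched))
})

test_that("day counts always partition the interval exactly", {
  set.seed(11)
  sched <- study_tariff()
  for (i in 1:60) {
    start <- as.Date("2013-10-01") + sample(0:500, 1)
    end <- start + sample(1:900, 1)
    sp <- split_days_by_period(start, end, sched)
    expect_equal(sum(sp$days), as.integer(end - start))
    expect_true(all(sp$days > 0))
  }
})

test_that("coverage errors name the uncovered date", {
  expect_error(split_days_by_period("2012-12-25", "2013-02-01", study_tariff()),
               "2012-12-25 predates")
  expect_error(split_days_by_period("2014-01-05", "2014-01-05", study_tariff()),
               "start < end")
})

test_that("cohort accrual matches the day-by-day oracle on random cohorts and schedules", {
  set.seed(23)
  for (rep in 1:25) {
    sched <- random_schedule(sample(2:4, 1))
    n <- sample(1:6, 1)
    entry <- as.Date("2013-01-01") + sample(0:700, n, replace = TRUE)
    end <- entry + sample(1:800, n, replace = TRUE)
    cohort <- data.frame(patient_id = sprintf("P%d", 1:n),
                         entry_date = entry, end_date = end)
    oc <- outsourced_cost(cohort, sched)
    oracle <- sum(vapply(seq_len(n), function(i)
      day_loop_cost_cents(entry[i], end[i], sched), numeric(1)))
    expect_equal(cents(oc$total), oracle)
    # per-patient accruals sum to the total
    expect_equal(sum(round(oc$per_patient$cost_eur * 100)), cents(oc$total))
  }
})

test_that("empty cohorts cost zero and rate raises never decrease cost", {
  expect_equal(cents(outsourced_cost(data.frame(), study_tariff())$total), 0)
  base <- study_tariff()
  raised <- tariff_schedule(base$start, base$end - 1L,
                            base$rate_cents / 100 + c(0, 0.10, 0))
  cohort <- data.frame(patient_id = "P1", entry_date = "2013-11-01",
                       end_date = "2016-11-01")
  expect_gte(cents(outsourced_cost(cohort, raised)$total),
             cents(outsourced_cost(cohort, base)$total))
})
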