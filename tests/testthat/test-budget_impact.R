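test_that("projection rows satisfy the difference identities", {
  rows <- study_projection()
  expect_equal(nrow(rows), 5L)
  expect_equal(round(rows$difference_eur * 100),
               round(rows$traditional_eur * 100) -
                 round(rows$alternative_eur * 100))
  expect_equal(rows$difference_pct,
               round_half_up(100 * rows$difference_eur / rows$traditional_eur, 2))
  # the shipped printed columns agree with recomputation: no flags
  expect_length(attr(rows, "flags"), 0)
})

test_that("column totals and percentages follow the published table", {
  tc <- table_consistency(study_projection())
  expect_equal(eur(tc$total_difference), 1063026.04)
  expect_equal(tc$total_difference_pct, 46.09)
  r2016 <- study_projection()[study_projection()$year == 2016, ]
  expect_equal(r2016$difference_pct, 55.64)
  # column sums are exact in cents even where printed totals rounded
  expect_equal(eur(tc$total_traditional), 2306499.67)
  expect_equal(eur(tc$total_alternative), 1243473.63)
})

test_that("supplied difference columns that contradict the costs are flagged", {
  rows <- projection_table(2015:2016, c(100, 110), c(60, 60),
                           difference_eur = c(40, 49.50))
  expect_length(attr(rows, "flags"), 1)
  expect_match(attr(rows, "flags"), "2016")
  # recomputed values win in the emitted rows
  expect_equal(rows$difference_eur, c(40, 50))
})

test_that("generated projections compound growth and repurchase devices on schedule", {
  spec <- projection_spec(2015, 7, money(100), 0.10,
                          alternative_recurrent_cost = money(40),
                          device_investment_cost = money(30),
                          device_lifetime_years = 5)
  rows <- project(spec)
  expect_equal(rows$traditional_eur[2], 110)
  expect_equal(rows$traditional_eur, round_half_up(100 * 1.1^(0:6), 2))
  # device bought in year 1 and again in year 6
  expect_equal(rows$alternative_eur, c(70, 40, 40, 40, 40, 70, 40))
  # zero growth, equal arms: every difference is zero
  flat <- project(projection_spec(2015, 3, money(50), 0,
                                  alternative_year_costs = money(rep(50, 3))))
  expect_true(all(flat$difference_eur == 0))
  expect_true(all(flat$difference_pct == 0))
  # horizon 0 gives an empty projection
  expect_equal(nrow(project(projection_spec(2015, 0, money(50), 0,
                                            alternative_year_costs = money(numeric(0))))),
               0L)
})

test_that("the published traditional column compounds at a constant rate", {
  rows <- study_projection()
  ratios <- rows$traditional_eur[-1] / rows$traditional_eur[-5]
  expect_equal(ratios, rep(1.1023, 4), tolerance = 1e-4)
})

test_that("price scenarios scale only the device share and are affine", {
  rows <- study_projection()
  share <- round(rows$alternative_eur * 0.4667 * 100) / 100
  expect_error(apply_scenario(rows, 0, share), "positive")
  expect_error(apply_scenario(rows, 1.2, rows$alternative_eur + 1), "within")
  # identity at multiplier 1
  base <- apply_scenario(rows, 1, share)
  expect_equal(base$alternative_eur, rows$alternative_eur)
  # +50% on a 100-euro share raises that year's cost by exactly 50
  one <- projection_table(2015, 1000, 400)
  up <- apply_scenario(one, 1.5, 100)
  expect_equal(up$alternative_eur, 450)
  # affine up to per-year cent quantization:
  # cost(1.5) - cost(1.25) == cost(1.25) - cost(1.0)
  a <- table_consistency(apply_scenario(rows, 1.0, share))$total_alternative
  b <- table_consistency(apply_scenario(rows, 1.25, share))$total_alternative
  c <- table_consistency(apply_scenario(rows, 1.5, share))$total_alternative
  expect_lte(abs((cents(b) - cents(a)) - (cents(c) - cents(b))), nrow(rows))
})

test_that("savings are non-increasing in the device-price multiplier", {
  suite <- scenario_suite(study_projection())
  expect_equal(suite$multiplier, c(1, 1.25, 1.5))
  expect_true(all(diff(suite$total_difference_eur) < 0))
  expect_true(all(diff(suite$total_difference_pct) < 0))
  expect_equal(suite$total_difference_eur[1], 1063026.04)
  # post-investment years keep a positive difference even at +50%
  worst <- apply_scenario(study_projection(), 1.5,
                          round(study_projection()$alternative_eur * 0.4667 * 100) / 100)
  expect_true(all(worst$difference_eur[worst$year >= 2016] > 0))
})
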