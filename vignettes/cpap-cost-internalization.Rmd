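---
title: "Costing internalized versus outsourced CPAP provision: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing internalized versus outsourced CPAP provision: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpapcost)
```

## The problem

Continuous positive airway pressure (CPAP) is the first-line therapy for
sleep apnea-hypopnea syndrome. In Spain and much of Europe, home CPAP is
provided by an external contractor that bills the health system a flat
daily rental rate per device. An alternative is *internalization*: the
hospital buys the devices and accessories outright and runs therapy
follow-up with its own nursing staff. Because the patient receives the
same device and the same follow-up schedule either way, effectiveness is
taken as equal and the comparison is a **cost-minimization analysis**:
only direct costs are compared.

`cpapcost` implements that comparison for a 21-patient pilot cohort
(4 patients newly started on CPAP, 17 already on therapy, recruited
October–December 2013 and followed to October 2016, 23,046 patient-days
in total), plus a health-area **budget-impact** projection and a
deterministic device-price sensitivity analysis.

## The two costing arms

**Outsourced arm.** The contractor bills per device and day. The daily
rate changed twice during follow-up, so each patient's follow-up span is
partitioned across a piecewise-constant tariff schedule:

| period | rate |
|---|---|
| study entry through 31 Jan 2014 | € 1.10 / device-day |
| 1 Feb – 6 Jul 2014 | € 0.86 / device-day |
| 7 Jul 2014 onwards | € 0.65 / device-day |

Intervals are half-open `[start, end)`; "through 31 January" keeps
31 January on the first rate, which makes the periods contiguous and
every queried day covered by exactly one period. `split_days_by_period()`
partitions a follow-up interval (day counts always sum exactly to the
interval length) and `outsourced_cost()` accrues days × rate over a
cohort. The tests additionally check the accrual against a deliberately
naive day-by-day loop on randomized cohorts and schedules.

For the study cohort itself the contracted total (€ 22,781.18) is an
**exogenous input**: the per-patient billing detail behind it was never
published, and over 23,046 days it implies a mean € 0.99/day that cannot
be reconstructed from mostly rate-3 follow-up alone. We deliberately do
not guess at the contractor's billing detail; the figure enters the
comparison as given, and the accrual engine is validated on synthetic
cohorts instead.

**Internalized arm.** Bottom-up microcosting: every device and accessory
handed out over follow-up is priced at its retail unit cost (VAT
included) and charged **in full at acquisition** — no annualization over
the device's 5-year useful life. This overstates the internalized cost
in the purchase year and is therefore conservative against the
internalization hypothesis; it also reflects cash actually spent.
Structure costs (space, administration) and supplies (electricity,
water) are outside the perimeter on both arms. Nursing follow-up is
imputed as whole workdays at the collective-agreement daily wage of
€ 153.51. The workday count is not published; the only count consistent
with the published totals is 6 (the residual € 921.06 divided by the
daily wage is exactly 6), so 6 is the default of an explicit parameter,
never a hidden constant.

## Currency and rounding

All amounts are integer euro cents (`money`), and every sum, product
and difference is exact; floating point appears only when a division or
an explicit rounding step asks for it. Published figures mix rounding
conventions: per-device-day costs round half-up on the cent
(€ 6825.11 / 23,046 → € 0.30), while per-patient subgroup averages are
truncated (€ 12,890.69 / 17 = 758.275… → € 758.27). Rounding mode is
therefore an explicit argument everywhere, and reports carry the
unrounded value next to every rounded one so nothing downstream
accumulates rounding error.

## Headline metrics

```{r}
agg <- study_aggregates()
cons <- consumables_total(study_catalogue(), study_usage_quantities())
internal <- internal_total(cons$total,
                           nursing_cost(agg$nursing_workdays,
                                        agg$nursing_daily_wage))
cmp <- cost_comparison(internal, agg$outsourced_total, agg$patient_days,
                       agg$n_new, agg$n_prevalent, agg$subgroup_savings)
cmp
```

The subgroup savings (new vs prevalent patients) are published
aggregates; the constructor enforces that they decompose the total
saving exactly in cents.

## Budget impact and price sensitivity

The published health-area extrapolation (population 135,136, years
2015–2019) does not state its uptake or growth assumptions, and the
alternative-arm yearly growth is non-constant, so those rows are not
re-derivable. The package therefore ships the yearly arm costs as a
fixture and **verifies the table's arithmetic** (`table_consistency()`):
row identities difference = traditional − alternative, percentages
half-up to 2 decimals, and column totals. The printed traditional and
alternative column totals each differ from their column sums by € 0.01
(row-level rounding in the source table); the difference column is
exact, so totals are recomputed as sums and the difference column is the
pinned quantity. A parameterized projector (`project()`) is provided for
forward use: the traditional arm compounds at a constant growth rate
(the published rows imply a constant factor ≈ 1.1023), and the
alternative arm repurchases devices in the investment year and every
`device_lifetime_years` (default 5) thereafter, consistent with the
no-annualization costing.

`apply_scenario()` scales the device-attributable component of each
alternative-arm year by a price multiplier (base 1.0, +25%, +50%),
leaving non-device components untouched. The published table does not
break out a device share per year, so the default share is the cohort's
own device fraction of internalized spending, 3185.28 / 6825.11 ≈ 46.7%;
the qualitative conclusions (identity at 1.0, savings non-increasing in
the multiplier, positive post-investment differences at +50%) hold for
any share between 0 and 100%, which the tests exercise.

```{r}
rows <- study_projection()
scenario_suite(rows, c(1, 1.25, 1.5))
```

## Survey statistics

Satisfaction was surveyed on 4-level items; patients new to CPAP
answered only for the internalized system, so the internalized column
has 21 respondents and the external column 17. Distributions are
compared with a Pearson chi-square without continuity correction and no
multiple-testing adjustment. Several expected counts fall below 5 — the
classic validity rule is violated, and `chi_square_test()` surfaces that
as a warning rather than silently fixing it. Because the source analysis
reports the satisfaction item below the 0.001 landmark while the full
sparse 4×2 table gives p = 0.0021, the function also exposes
`collapse = "binary"` (top category vs rest), under which p = 0.00024;
the quality-of-service item reaches p = 0.0008 on the full table once
its all-zero row is dropped. Both readings are reported side by side and
neither is asserted to be the source's exact computation. Fisher's exact
test (2×2, two-sided, hypergeometric) is available for small tables and
is tested against an exhaustive enumeration oracle for every 2×2 table
with n ≤ 20. Preference percentages use the 17 patients able to compare
both systems as denominator, half-up to one decimal.

## The synthetic cohort generator

Per-patient follow-up timelines and replacement dates were never
published, so the generator (`generate_cohort()`) stands in for them and
makes every pipeline stage testable end to end. It emulates:

* entry dates uniform over the recruitment window
  `[2013-10-01, 2014-01-01)`, follow-up to 2016-11-01 (exclusive;
  "followed until October 2016" read as through the end of October) —
  in expectation ≈ 22,712 patient-days, within 5% of the observed
  23,046;
* the exact 4 new / 17 prevalent split (counts, not probabilities);
* one device (with its tubing) issued deterministically at entry;
* consumable replacements as independent Poisson processes — the
  minimal-assumption counting process given that only aggregate
  quantities are known — with per-patient-year rates calibrated by
  `calibrate_to_table1()` so expected counts match the consumption
  table (e.g. 45 nasal masks over ≈ 63 patient-years → 0.714/patient-year);
* optional exponential dropout (default 0: none was reported);
* multinomial survey responses from configurable distributions.

Everything is reproducible from a single integer seed, and generation
restores the caller's RNG state. What the generator does **not**
emulate: clinical covariates (AHI, BMI, adherence hours), seasonal or
wear-dependent replacement clustering, multiple simultaneously billed
devices per patient, and the contractor's actual billing detail — so
synthetic results validate the *mechanics* (accrual, costing,
invariants), not the study's printed outsourced total.

## Numerical choices and edge cases

* Money construction rejects sub-cent amounts; multiplying money by a
  non-integer must still land on a whole cent or it errors.
* Half-up rounding uses a magnitude-scaled tolerance before `floor(x + 0.5)`
  so binary representation error at the .5 boundary cannot flip a cent.
* Scenario scaling rounds the scaled device component to cents once per
  year; affinity in the multiplier is therefore exact up to one cent per
  projected year, which is the tolerance the tests use.
* Degenerate inputs error early with named context: empty tariff
  coverage names the uncovered date, non-contiguous schedules name the
  gap, usage events outside follow-up name the patient and dates,
  zero denominators refuse to divide. An empty cohort is not an error:
  it costs € 0.00 throughout.
* Problem sizes in the test suite: 100+ random-cohort accrual
  comparisons, the exhaustive n ≤ 20 Fisher sweep (~10,600 tables) and
  200 calibration seeds — together they keep the suite near ten seconds
  while still exercising every invariant.

## Known limitations

Adherence effects, storage/overhead/supply costs and the € 5000
budget-limit recruitment rule are out of scope, mirroring the source
analysis's perimeter. The projection engine is only as good as its
parameterization: the published extrapolation's assumptions are
unrecoverable, so the package verifies that table rather than claiming
to re-derive it. Cost levels are specific to Spanish tariffs and prices
around 2013–2019; the mechanics (tariff accrual, microcosting,
budget-impact arithmetic) are general.
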