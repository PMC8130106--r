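# Independent oracles, deliberately naive: these re-derive expected
# values by brute force and must stay decoupled from the package's own
# code paths.

# day-by-day rental accrual: walk every calendar day of [start, end),
# look up its rate, sum cents
day_loop_cost_cents <- function(start, end, schedule) {
  days <- seq(as.Date(start), as.Date(end) - 1L, by = "day")
  total <- 0
  for (d in days) {
    d <- as.Date(d, origin = "1970-01-01")
    hit <- which(schedule$start <= d & (is.na(schedule$end) | d < schedule$end))
    stopifnot(length(hit) == 1L)
    total <- total + schedule$rate_cents[hit]
  }
  total
}

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins
fisher_enum_p <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# closed-form Pearson statistic for a 2x2 table from its marginals
chisq_2x2_stat <- function(m) {
  n <- sum(m)
  num <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 * n
  num / (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
}

# random cent-exact tariff schedule starting 2013-01-01 with k periods
random_schedule <- function(k = 3L) {
  origin <- as.Date("2013-01-01")
  bounds <- origin + sort(sample(30:1200, k - 1L))
  starts <- c(origin, bounds)
  ends_incl <- c(bounds - 1L, as.Date(NA))
  rates <- sample(5:250, k) / 100
  tariff_schedule(starts, ends_incl, rates)
}

study_satisfaction_table <- function() {
  survey_question_table(study_survey(), "satisfaction")
}
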