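test_that("hazard-to-probability conversion is exact", {
  expect_equal(hazard_to_probability(0), 0)
  expect_equal(hazard_to_probability(log(2)), 0.5, tolerance = 1e-12)
  # small-rate Taylor series: r - r^2/2 + r^3/6
  r <- 0.01
  expect_equal(hazard_to_probability(r), r - r^2 / 2 + r^3 / 6,
               tolerance = 1e-6)
  expect_equal(round(hazard_to_probability(0.01), 5), 0.00995)
  expect_error(hazard_to_probability(-0.1), "non-negative")
})

test_that("disease-free cohort reproduces brute-force life-table expectancy", {
  lt <- gompertz_life_table()
  spec <- markov_spec("no_screening", incidence = 0, p_benign = 0,
                      discount_rate = 0)
  out <- run_cohort(spec, lt)
  # independent oracle: curtate survival sums straight off the table
  p_alive <- cumprod(1 - lt$qx)
  expect_equal(out$life_years, 1 + sum(p_alive), tolerance = 1e-9)
  expect_equal(out$life_years, out$qalys)
  expect_equal(out$cost, 0)
})

test_that("occupancy is conserved and death states are absorbing", {
  lt <- gompertz_life_table()
  out <- run_cohort(markov_spec("screening"), lt)
  sums <- rowSums(out$trace)
  expect_lt(max(abs(sums - 1)), 1e-12)
  for (st in c("oc_death", "other_death"))
    expect_true(all(diff(out$trace[, st]) >= -1e-15))
  expect_true(all(out$trace >= -1e-15))
})

test_that("a two-state toy cohort gives the geometric-series life expectancy", {
  lt <- structure(data.frame(age = 60:120,
                             qx = c(rep(0.5, 60), 1)),
                  class = c("life_table", "data.frame"))
  spec <- markov_spec("no_screening", incidence = 0, p_benign = 0,
                      discount_rate = 0)
  out <- run_cohort(spec, lt)
  expect_equal(out$life_years, 2, tolerance = 1e-6)
})

test_that("QALYs equal life-years under unit utilities and fall below them otherwise", {
  lt <- gompertz_life_table()
  unit <- markov_spec("screening",
                      utilities = c(well = 1, benign_ooph = 1,
                                    early_oc = 1, advanced_oc = 1))
  out <- run_cohort(unit, lt)
  expect_equal(out$qalys, out$life_years, tolerance = 1e-12)
  base <- run_cohort(markov_spec("screening"), lt)
  expect_lt(base$qalys, base$life_years)
})

test_that("strategy comparison sits in the trade-off quadrant on default calibration", {
  lt <- gompertz_life_table()
  cmp <- compare_strategies(markov_spec("screening"),
                            markov_spec("no_screening"), lt)
  expect_gt(cmp$delta_cost, 0)
  expect_gt(cmp$delta_qaly, 0)
  expect_gt(cmp$delta_ly, 0)
  expect_equal(cmp$icer$classification, "tradeoff")

  same <- compare_strategies(markov_spec("no_screening"),
                             markov_spec("no_screening"), lt)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_equal(same$icer$classification, "undefined")
})

test_that("ICER responds monotonically to costs and the stage shift", {
  lt <- gompertz_life_table()
  none <- markov_spec("no_screening")
  icer_at <- function(tc) {
    compare_strategies(markov_spec("screening", test_cost = tc), none,
                       lt)$icer$ratio
  }
  icers <- vapply(c(15, 30, 50), icer_at, numeric(1))
  expect_true(all(diff(icers) > 0))
  # a stronger early-stage shift improves cost-effectiveness
  lo <- compare_strategies(markov_spec("screening", early_fraction = 0.35),
                           none, lt)$icer$ratio
  hi <- compare_strategies(markov_spec("screening", early_fraction = 0.55),
                           none, lt)$icer$ratio
  expect_lt(hi, lo)
})

test_that("invalid transition budgets are rejected before simulation", {
  lt <- gompertz_life_table()
  bad <- markov_spec("screening", incidence = 0.7, p_benign = 0.5)
  expect_error(run_cohort(bad, lt), "exceed 1")
  expect_error(compare_strategies(
    markov_spec("screening", discount_rate = 0.015),
    markov_spec("no_screening", discount_rate = 0.035), lt),
    "discount")
})

test_that("PSA is deterministic, degenerate at a point mass, and boundary-monotone", {
  lt <- gompertz_life_table()
  s <- markov_spec("screening")
  n <- markov_spec("no_screening")
  point <- psa(s, n, lt, test_cost_range = c(20, 20), n_draws = 5,
               seed = 4)
  base <- compare_strategies(s, n, lt)$icer$ratio
  expect_true(all(abs(point$draws$icer - base) < 1e-9))

  p1 <- psa(s, n, lt, test_cost_range = c(15, 50), n_draws = 40, seed = 8)
  p2 <- psa(s, n, lt, test_cost_range = c(15, 50), n_draws = 40, seed = 8)
  expect_identical(p1$draws, p2$draws)
  # ICER strictly increases with the drawn test cost, so the sample
  # extremes occur at the boundary draws
  ord <- order(p1$draws$test_cost)
  expect_true(all(diff(p1$draws$icer[ord]) > 0))
  expect_equal(which.min(p1$draws$icer), which.min(p1$draws$test_cost))
  expect_equal(which.max(p1$draws$icer), which.max(p1$draws$test_cost))
  expect_true(p1$summary[["min"]] < base && base < p1$summary[["max"]])
  expect_error(psa(s, n, lt, test_cost_range = c(50, 15)), "lo <= hi")
})
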