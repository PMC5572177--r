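test_that("ICER ratio and dominance classification follow the cost-effectiveness plane", {
  r <- compute_icer(256, 0.0028)
  expect_equal(r$ratio, 256 / 0.0028)
  expect_equal(r$classification, "tradeoff")
  # printed ratios differ from straight division only by rounding
  expect_lt(abs(r$ratio - 91452) / 91452, 0.001)
  r2 <- compute_icer(427, 0.01421)
  expect_lt(abs(r2$ratio - 30033) / 30033, 0.001)
  expect_equal(compute_icer(-1, 0.1)$classification, "dominant")
  expect_equal(compute_icer(5, -0.1)$classification, "dominated")
  expect_equal(compute_icer(-5, -0.1)$classification, "tradeoff")
  u <- compute_icer(5, 0)
  expect_equal(u$classification, "undefined")
  expect_true(is.na(u$ratio))
})

test_that("Fieller interval collapses, bounds and degenerates correctly", {
  exact <- fieller_ci(256, 0.0028, 0, 0, 0)
  expect_true(exact$bounded)
  expect_equal(exact$lower, 256 / 0.0028, tolerance = 1e-9)
  expect_equal(exact$upper, 256 / 0.0028, tolerance = 1e-9)
  # effect not significantly nonzero: unbounded set, never truncated
  deg <- fieller_ci(256, 0.0028, 100, 1, 0)
  expect_false(deg$bounded)
  expect_equal(deg$lower, -Inf)
  expect_error(fieller_ci(1, 1, -1, 0, 0), "outside")
  expect_error(fieller_ci(1, 1, 1, 1, 0, alpha = 2), "alpha")
})

test_that("Fieller bounds match the Monte-Carlo ratio distribution", {
  dc <- 256; de <- 0.0028; sc <- 10; se <- 1e-4
  ci <- fieller_ci(dc, de, sc^2, se^2, 0, alpha = 0.05)
  set.seed(99)
  draws <- rnorm(1e6, dc, sc) / rnorm(1e6, de, se)
  q <- unname(quantile(draws, c(0.025, 0.975)))
  expect_true(ci$bounded)
  expect_lt(abs(ci$lower - q[1]), 150)
  expect_lt(abs(ci$upper - q[2]), 150)
  expect_true(ci$lower <= dc / de && dc / de <= ci$upper)
})

test_that("Fieller width shrinks to zero with the variances", {
  w <- vapply(c(1, 0.1, 0.01), function(f) {
    ci <- fieller_ci(100, 0.01, f * 25, f * 1e-6, 0)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_lt(w[3], w[1] / 5)
})

test_that("Fieller agrees with a percentile bootstrap of the ratio on synthetic data", {
  tr <- boosted_trial(n = 2000, seed = 7)
  res <- icer_within_trial(tr, discount_rate = 0.015, n_bootstrap = 400,
                           seed = 5)
  expect_true(res$delta_effect > 0)
  # independent percentile bootstrap of the ratio itself
  ctl <- subset(tr, arm == "control")
  mms <- subset(tr, arm == "mms")
  horizon <- min(max(ctl$followup_time), max(mms$followup_time))
  one_rep <- function(sub) {
    idx <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
    s <- sub[idx, ]
    km <- km_estimate(s)
    eff <- restricted_mean(km, min(horizon, km$max_time), 0.015)$estimate
    cost <- lin_cost_estimate(s, discount_rate = 0.015,
                              n_bootstrap = 0)$mean
    c(cost, eff)
  }
  set.seed(17)
  reps <- replicate(400, one_rep(mms) - one_rep(ctl))
  ratios <- reps[1, ] / reps[2, ]
  q <- unname(quantile(ratios, c(0.025, 0.975)))
  width <- q[2] - q[1]
  expect_true(res$bounded)
  expect_lt(abs(res$ci_low - q[1]), 0.25 * width)
  expect_lt(abs(res$ci_high - q[2]), 0.25 * width)
})

test_that("test-cost sweep is monotone and anchored at the base case", {
  des <- trial_design(3000, 1500, 1500, recruitment_window = 2,
                      max_followup = 12, screening_duration = 10)
  hz <- hazard_spec(baseline_oc_hazard = 0.01, late_hazard_ratio = 2,
                    lead_time = 3, reduction_mms = 0.5,
                    reduction_uss = 0.3)
  cm <- cost_model()
  sw <- univariate_sweep(des, hz, cm, c(15, 20, 30, 40, 50),
                         discount_rate = 0.015, seed = 42)
  expect_true(all(sw$delta_effect == sw$delta_effect[1]))
  expect_gt(sw$delta_effect[1], 0)
  expect_true(all(diff(sw$delta_cost) > 0))
  expect_true(all(diff(sw$icer) > 0))
  # unchanged test cost reproduces the base case exactly
  base <- icer_within_trial(generate_trial(des, hz, cm, seed = 42),
                            discount_rate = 0.015, n_bootstrap = 0)
  expect_equal(sw$icer[sw$test_cost == 20], base$ratio, tolerance = 1e-12)
  expect_error(univariate_sweep(des, hz, cm, numeric(0)), "empty")
  expect_error(univariate_sweep(des, hz, cm, -3), "negative")
})
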