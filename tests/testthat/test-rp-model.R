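test_that("df = 1 fit recovers exponential parameters within two standard errors", {
  set.seed(55)
  rec <- make_records(rexp(5000, 0.05), rep(1L, 5000))
  fit <- fit_rp_model(rec, df = 1)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$gamma[2] - 1), 2 * se[2])        # Weibull shape -> 1
  expect_lt(abs(fit$gamma[1] - log(0.05)), 2 * se[1])
  expect_true(fit$converged)
})

test_that("df = 1 is exactly Weibull: matches an independent Weibull MLE", {
  set.seed(56)
  death <- rweibull(3000, shape = 1.4, scale = 9)
  censor <- runif(3000, 2, 14)
  time <- pmin(death, censor)
  event <- as.integer(death <= censor)
  rec <- make_records(time, event)
  fit <- fit_rp_model(rec, df = 1)
  sr <- survival::survreg(survival::Surv(time, event) ~ 1,
                          dist = "weibull")
  shape <- 1 / sr$scale
  scale <- exp(coef(sr)[[1]])
  grid <- seq(0.5, 12, by = 0.5)
  s_rp <- rp_survival(fit, grid)
  s_weib <- exp(-(grid / scale)^shape)
  expect_lt(max(abs(s_rp - s_weib)), 1e-3)
  expect_lt(abs(fit$loglik - sr$loglik[1]), 0.01)
})

test_that("spline fit agrees with an independent flexible-parametric implementation", {
  tr <- boosted_trial(n = 2500, seed = 9)
  sub <- subset(tr, arm == "control")
  fit <- fit_rp_model(sub, df = 2)
  fx <- flexsurv::flexsurvspline(
    survival::Surv(followup_time, event) ~ 1, data = sub, k = 1,
    scale = "hazard")
  grid <- seq(0.5, 11, by = 0.5)
  s_fx <- summary(fx, t = grid, type = "survival", ci = FALSE,
                  tidy = TRUE)$est
  expect_lt(max(abs(rp_survival(fit, grid) - s_fx)), 0.005)
  expect_lt(abs(fit$aic - fx$AIC), 1)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_rp_model(make_records(c(1, 2, 3), c(0, 0, 0)), df = 1),
               "too few events")
  expect_error(fit_rp_model(make_records(rep(2, 50), rep(1, 50)), df = 1),
               "concentrated")
})

test_that("AIC selection returns the grid minimiser with ties toward small df", {
  tr <- boosted_trial(n = 2500, seed = 10)
  sub <- subset(tr, arm == "control")
  one <- select_by_aic(sub, df_grid = 2)
  expect_equal(one$df, 2L)
  best <- select_by_aic(sub, df_grid = 1:3)
  aics <- attr(best, "aic_grid")
  expect_length(aics, 3)
  expect_true(all(best$aic <= aics + 1e-9))
  expect_error(select_by_aic(sub, df_grid = integer(0)), "empty")
})

test_that("AIC prefers df = 1 in most replicates of Weibull data", {
  set.seed(77)
  picks <- replicate(30, {
    death <- rweibull(600, shape = 1.3, scale = 8)
    censor <- runif(600, 4, 15)
    rec <- make_records(pmin(death, censor),
                        as.integer(death <= censor))
    select_by_aic(rec, df_grid = 1:3)$df
  })
  expect_gt(mean(picks == 1), 0.5)
})

test_that("effect extrapolation matches quadrature on closed-form survival", {
  m_a <- exact_rp_model(0.05)  # exponential hazards 0.05 vs 0.08
  m_b <- exact_rp_model(0.08)
  km_a <- flat_km(10)
  km_b <- flat_km(10)
  res <- extrapolate_effects(m_a, m_b, km_a, km_b, horizon = 25,
                             discount_rate = 0.015, trial_end = 10)
  oracle_arm <- function(rate) {
    within <- sum(vapply(0:9, function(k) 1.015^(-k), numeric(1)))
    post <- sum(vapply(10:24, function(k) {
      f <- function(t) exp(-rate * t) / exp(-rate * 10)
      1.015^(-k) * integrate(f, k, k + 1, rel.tol = 1e-12)$value
    }, numeric(1)))
    within + post
  }
  expect_equal(res$ly_a, oracle_arm(0.05), tolerance = 1e-6)
  expect_equal(res$delta, oracle_arm(0.05) - oracle_arm(0.08),
               tolerance = 1e-6)

  same <- extrapolate_effects(m_a, m_a, km_a, km_a, horizon = 25,
                              discount_rate = 0.015, trial_end = 10)
  expect_equal(same$delta, 0, tolerance = 1e-12)
  # stronger discounting shrinks a positive gain
  res35 <- extrapolate_effects(m_a, m_b, km_a, km_b, horizon = 25,
                               discount_rate = 0.035, trial_end = 10)
  expect_lt(res35$delta, res$delta)
  expect_error(extrapolate_effects(m_a, m_b, km_a, km_b, horizon = 5,
                                   trial_end = 10), "exceed")
})

test_that("cost extrapolation reproduces finite-sum oracles", {
  near_flat <- exact_rp_model(1e-12)
  # certain survival, survivor cost only: 11 whole years at 50 pounds
  expect_equal(extrapolate_costs(near_flat, 50, 0, trial_end = 14,
                                 horizon = 25, discount_rate = 0),
               550, tolerance = 1e-6)
  # equal survivor and decedent costs collapse to sum of S(k)
  m <- exact_rp_model(0.1)
  s <- rp_survival(m, 14:24)
  expect_equal(extrapolate_costs(m, 80, 80, 14, 25, 0),
               sum(s) * 80, tolerance = 1e-9)
  # discounted two-component sum against direct arithmetic
  sk <- rp_survival(m, 14:25)
  oracle <- sum(1.015^-(14:24) *
                  (sk[-1] * 30 + (sk[-12] - sk[-1]) * 500))
  expect_equal(extrapolate_costs(m, 30, 500, 14, 25, 0.015), oracle,
               tolerance = 1e-9)
  # survival must be non-increasing over the extrapolation window
  rising <- exact_rp_model(0.5, shape = -1)
  expect_error(extrapolate_costs(rising, 10, 10, 14, 25, 0),
               "non-monotone")
})

test_that("survivor and decedent annual costs split as constructed", {
  time <- c(3, 1.5, 2.5)
  event <- c(0, 1, 1)
  costs <- rbind(c(10, 10, 10),
                 c(0, 500, 0),
                 c(20, 20, 400))
  rec <- make_records(time, event, costs = costs)
  cc <- annual_cost_components(rec)
  # survived person-years: p1 y0,y1,y2; p2 y0; p3 y0,y1
  expect_equal(cc$survivor_cost, mean(c(10, 10, 10, 0, 20, 20)))
  # death years: p2 in y1 (500), p3 in y2 (400)
  expect_equal(cc$decedent_cost, 450)
  expect_equal(cc$decedent_years, 2)
})
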