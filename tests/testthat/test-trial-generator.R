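test_that("generator returns the requested records deterministically", {
  des <- trial_design(n_control = 400, n_mms = 200, n_uss = 200)
  tr1 <- generate_trial(des, hazard_spec(), cost_model(), seed = 11)
  tr2 <- generate_trial(des, hazard_spec(), cost_model(), seed = 11)
  expect_identical(tr1, tr2)
  expect_equal(nrow(tr1), 800)
  expect_equal(as.vector(table(tr1$arm)), c(400, 200, 200))
  expect_true(all(tr1$followup_time > 0))
  expect_true(all(cost_cols <- as.matrix(
    tr1[grep("^cost_y", names(tr1))]) >= 0))
  # yearly costs vanish beyond each woman's follow-up
  cm <- as.matrix(tr1[grep("^cost_y", names(tr1))])
  for (i in sample(nrow(tr1), 50)) {
    k <- ceiling(tr1$followup_time[i])
    if (k < ncol(cm)) expect_equal(unname(sum(cm[i, (k + 1):ncol(cm)])), 0)
  }
  tr3 <- generate_trial(des, hazard_spec(), cost_model(), seed = 12)
  expect_false(identical(tr1$followup_time, tr3$followup_time))
})

test_that("changing one arm's size leaves the other arms' records intact", {
  des_a <- trial_design(n_control = 300, n_mms = 200, n_uss = 100)
  des_b <- trial_design(n_control = 300, n_mms = 50, n_uss = 100)
  tr_a <- generate_trial(des_a, hazard_spec(), cost_model(), seed = 5)
  tr_b <- generate_trial(des_b, hazard_spec(), cost_model(), seed = 5)
  expect_identical(subset(tr_a, arm == "control")$followup_time,
                   subset(tr_b, arm == "control")$followup_time)
  expect_identical(subset(tr_a, arm == "uss")$followup_time,
                   subset(tr_b, arm == "uss")$followup_time)
})

test_that("parameter validation rejects invalid designs and hazards", {
  expect_error(trial_design(n_control = 0), "positive")
  expect_error(trial_design(n_mms = -5), "positive")
  expect_error(hazard_spec(reduction_mms = 1), "\\[0, 1\\)")
  expect_error(hazard_spec(reduction_uss = -0.1), "\\[0, 1\\)")
  expect_error(hazard_spec(baseline_oc_hazard = -1), "outside")
  expect_error(trial_design(screening_duration = 20), "screening_duration")
  expect_error(cost_model(test_cost = -1), "outside")
})

test_that("zero recruitment window makes censoring administrative at max follow-up", {
  des <- trial_design(n_control = 500, n_mms = 100, n_uss = 100,
                      recruitment_window = 0, max_followup = 10,
                      screening_duration = 8)
  tr <- generate_trial(des, hazard_spec(), cost_model(), seed = 2)
  cens <- subset(tr, event == 0)
  expect_true(all(abs(cens$followup_time - 10) < 1e-12))
})

test_that("null screening effect gives arm-exchangeable event times", {
  hz <- hazard_spec(baseline_oc_hazard = 0.02, reduction_mms = 0,
                    reduction_uss = 0)
  tr <- generate_trial(trial_design(8000, 8000, 1000), hz, cost_model(),
                       seed = 3)
  tc <- subset(tr, arm == "control" & event == 1)$followup_time
  tm <- subset(tr, arm == "mms" & event == 1)$followup_time
  expect_gt(suppressWarnings(stats::ks.test(tc, tm)$p.value), 0.01)
  # event proportions agree within Monte-Carlo noise
  pc <- mean(subset(tr, arm == "control")$event)
  pm <- mean(subset(tr, arm == "mms")$event)
  se <- sqrt(pc * (1 - pc) * 2 / 8000)
  expect_lt(abs(pc - pm), 3 * se)
})

test_that("screening accrues non-negative extra cost when treatment is held equal", {
  # null mortality effect and a common stage distribution isolate the
  # mechanical cost of screening itself
  hz <- hazard_spec(baseline_oc_hazard = 0.01, late_hazard_ratio = 2,
                    lead_time = 3, reduction_mms = 0, reduction_uss = 0)
  cm_eq <- cost_model(early_fraction_screened = 0.3,
                      early_fraction_control = 0.3)
  tr <- generate_trial(trial_design(3000, 1500, 1500,
                                    recruitment_window = 2,
                                    max_followup = 12,
                                    screening_duration = 10),
                       hz, cm_eq, seed = 42)
  cm <- as.matrix(tr[grep("^cost_y", names(tr))])
  tot <- rowSums(cm)
  expect_gte(mean(tot[tr$arm == "mms"]), mean(tot[tr$arm == "control"]))
  expect_gte(mean(tot[tr$arm == "uss"]), mean(tot[tr$arm == "mms"]))
})

test_that("closed-form restricted mean matches exponential theory", {
  flat <- hazard_spec(baseline_oc_hazard = 0, late_hazard_ratio = 1)
  expect_equal(true_rmst(flat, "control", 10, 0), 10, tolerance = 1e-12)
  expo <- hazard_spec(baseline_oc_hazard = 0.1, late_hazard_ratio = 1)
  expect_equal(true_rmst(expo, "control", 5, 0), (1 - exp(-0.5)) / 0.1,
               tolerance = 1e-10)
  expect_lt(true_rmst(expo, "control", 10, 0),
            true_rmst(flat, "control", 10, 0))
})

test_that("closed-form restricted mean matches numerical quadrature with discounting", {
  hz <- hazard_spec()
  rates <- c(hz$baseline_oc_hazard,
             hz$baseline_oc_hazard * hz$late_hazard_ratio *
               (1 - hz$reduction_mms))
  surv <- function(t) exp(-(rates[1] * pmin(t, 7) +
                              rates[2] * pmax(t - 7, 0)))
  oracle <- sum(vapply(0:13, function(k) {
    hi <- min(k + 1, 13.6)
    if (hi <= k) return(0)
    1.015^(-k) * integrate(surv, k, hi, rel.tol = 1e-12)$value
  }, numeric(1)))
  expect_equal(true_rmst(hz, "mms", 13.6, 0.015), oracle,
               tolerance = 1e-9)
})

test_that("empirical Kaplan-Meier restricted mean converges to the analytic value", {
  tr <- default_trial()
  hz <- attr(tr, "hazard")
  km <- km_estimate(tr, "control")
  r <- restricted_mean(km, discount_rate = 0.015)
  truth <- true_rmst(hz, "control", r$horizon, 0.015)
  expect_lt(abs(r$estimate - truth), 2 * r$std_error)
})
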