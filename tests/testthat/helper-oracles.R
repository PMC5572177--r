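# Shared fixtures and independent oracles for the test suite.

# Build an oc_trial-shaped data frame from raw vectors (cost matrix optional).
make_records <- function(time, event, arm = "control", costs = NULL) {
  n <- length(time)
  if (is.null(costs)) costs <- matrix(0, n, max(1, ceiling(max(time))))
  colnames(costs) <- paste0("cost_y", seq_len(ncol(costs)) - 1L)
  df <- data.frame(id = sprintf("X%04d", seq_len(n)),
                   arm = factor(rep_len(arm, n),
                                levels = c("control", "mms", "uss")),
                   followup_time = time, event = event,
                   diagnosis_year = NA_integer_, stage = NA_character_)
  cbind(df, as.data.frame(costs))
}

# Brute-force Kaplan-Meier by explicit risk-set enumeration (deaths before
# censorings at ties).
km_oracle <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  surv <- numeric(length(dt))
  s <- 1
  for (i in seq_along(dt)) {
    at_risk <- sum(time >= dt[i])
    deaths <- sum(time == dt[i] & event == 1)
    s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  list(times = dt, survival = surv)
}

# Rectangle-rule area under a right-continuous step survival curve on
# [0, tau], optionally with annual discount weights: independent of the
# package's segment bookkeeping (brute-force fine grid).
step_area_oracle <- function(times, survival, tau, rate = 0, dt = 1e-4) {
  grid <- seq(0, tau - dt, by = dt)
  s <- vapply(grid, function(g) {
    i <- sum(times <= g)
    if (i == 0) 1 else survival[i]
  }, numeric(1))
  sum((1 + rate)^(-floor(grid)) * s * dt)
}

# A small trial with an amplified screening effect: enough events that
# effect differences are sign-stable at modest n. Used for property tests
# of the estimator machinery (not for calibration checks).
boosted_trial <- function(n = 3000, seed = 42) {
  generate_trial(
    trial_design(n_control = n, n_mms = n %/% 2, n_uss = n %/% 2,
                 recruitment_window = 2, max_followup = 12,
                 screening_duration = 10),
    hazard_spec(baseline_oc_hazard = 0.01, late_hazard_ratio = 2,
                lead_time = 3, reduction_mms = 0.5, reduction_uss = 0.3),
    cost_model(), seed = seed)
}

# Default-calibration trial at full scale, generated once per test run.
.trial_cache <- new.env(parent = emptyenv())
default_trial <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.trial_cache[[key]]))
    .trial_cache[[key]] <- generate_trial(trial_design(), hazard_spec(),
                                          cost_model(), seed = seed)
  .trial_cache[[key]]
}

# Hand-built Royston-Parmar model object representing an exact
# exponential/Weibull survival law: ln H(t) = ln(rate) + shape * ln t.
exact_rp_model <- function(rate, shape = 1) {
  structure(list(df = 1L, gamma = c(log(rate), shape), knots = c(-5, 5),
                 loglik = NA_real_, aic = NA_real_,
                 vcov = matrix(NA, 2, 2), n = 0L, n_event = 0L,
                 converged = TRUE, arm = "toy"),
            class = "rp_model")
}

# KM curve object for a cohort with no observed events up to max_time.
flat_km <- function(max_time, n = 100L) {
  structure(list(times = numeric(0), survival = numeric(0),
                 at_risk = integer(0), n_event = integer(0),
                 std_err = numeric(0), n = n, max_time = max_time,
                 arm = "toy"),
            class = "km_curve")
}
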