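# Incremental cost-effectiveness ratios, Fieller intervals, and the
# univariate test-cost sensitivity sweep.

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' @param delta_cost incremental cost (pounds).
#' @param delta_effect incremental effect (life-years or QALYs).
#' @return An object of class `icer_result` with the ratio (absent when the
#'   effect difference is zero) and a classification on the
#'   cost-effectiveness plane: `tradeoff` (positive ratio quadrants),
#'   `dominant` (cheaper and more effective), `dominated` (costlier and
#'   less effective) or `undefined` (zero effect difference).
#' @examples
#' compute_icer(256, 0.0028)   # ~91429 per life-year gained
#' compute_icer(-1, 0.1)       # dominant
#' @export
compute_icer <- function(delta_cost, delta_effect) {
  stop_if_not_scalar(delta_cost, "delta_cost")
  stop_if_not_scalar(delta_effect, "delta_effect")
  if (delta_effect == 0) {
    cls <- "undefined"
    ratio <- NA_real_
  } else {
    ratio <- delta_cost / delta_effect
    cls <- if (delta_cost < 0 && delta_effect > 0) "dominant"
           else if (delta_cost > 0 && delta_effect < 0) "dominated"
           else "tradeoff"
  }
  structure(list(delta_cost = delta_cost, delta_effect = delta_effect,
                 ratio = ratio, classification = cls,
                 ci_low = NA_real_, ci_high = NA_real_, bounded = NA,
                 alpha = NA_real_),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  if (x$classification == "undefined") {
    cat("ICER undefined (zero effect difference)\n")
  } else {
    cat(sprintf("ICER: £%.0f per unit effect (dC = £%.2f, dE = %.5f) [%s]\n",
                x$ratio, x$delta_cost, x$delta_effect, x$classification))
  }
  if (isTRUE(x$bounded))
    cat(sprintf("  %.0f%% Fieller CI: £%.0f to £%.0f\n",
                100 * (1 - x$alpha), x$ci_low, x$ci_high))
  else if (identical(x$bounded, FALSE))
    cat("  Fieller set unbounded: effect not significantly nonzero\n")
  invisible(x)
}

#' Fieller confidence interval for a ratio of means
#'
#' Confidence limits for \eqn{R = \Delta C / \Delta E} as the roots of
#' \deqn{(\Delta E^2 - z^2 v_E) R^2 - 2 (\Delta C \Delta E - z^2 v_{CE}) R
#'       + (\Delta C^2 - z^2 v_C) = 0,}
#' with \eqn{z} the standard-normal \eqn{1-\alpha/2} quantile. When the
#' leading coefficient is not positive the effect difference is not
#' significantly nonzero and the confidence set is unbounded (the
#' complement of an interval, or the whole line); this is reported via
#' `bounded = FALSE`, never truncated to a finite interval.
#'
#' @param delta_cost,delta_effect incremental cost and effect.
#' @param var_cost,var_effect,covariance their variances and covariance.
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @return A list with `lower`, `upper`, `bounded`, `alpha`.
#' @examples
#' fieller_ci(256, 0.0028, var_cost = 100, var_effect = 1e-8,
#'            covariance = 0)
#' @export
fieller_ci <- function(delta_cost, delta_effect, var_cost, var_effect,
                       covariance = 0, alpha = 0.05) {
  stop_if_not_scalar(var_cost, "var_cost", lower = 0)
  stop_if_not_scalar(var_effect, "var_effect", lower = 0)
  stop_if_not_scalar(covariance, "covariance")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  z2 <- qnorm(1 - alpha / 2)^2
  a <- delta_effect^2 - z2 * var_effect
  b <- delta_cost * delta_effect - z2 * covariance
  c_ <- delta_cost^2 - z2 * var_cost
  if (a <= 0)
    return(list(lower = -Inf, upper = Inf, bounded = FALSE, alpha = alpha))
  disc <- b^2 - a * c_
  if (disc < 0) {
    # numerically possible only at the boundary of significance
    return(list(lower = -Inf, upper = Inf, bounded = FALSE, alpha = alpha))
  }
  roots <- sort(c((b - sqrt(disc)) / a, (b + sqrt(disc)) / a))
  list(lower = roots[1], upper = roots[2], bounded = TRUE, alpha = alpha)
}

#' Within-trial ICER with bootstrap-based Fieller interval
#'
#' Computes the incremental discounted cost (censoring-adjusted, via
#' [lin_cost_estimate()]) and incremental discounted restricted mean
#' survival between two arms, then a Fieller confidence interval. Variances
#' and the within-arm cost-effect covariances come from a shared
#' patient-level bootstrap (arms are independent, so between-arm
#' covariances vanish and within-arm ones add).
#'
#' @param records patient records.
#' @param arm,ref comparator and reference arm labels.
#' @param discount_rate annual discount rate applied to both costs and
#'   effects.
#' @param horizon restriction time for the survival effect; default is the
#'   larger arm-shared observed maximum.
#' @param alpha significance level for the Fieller interval.
#' @param n_bootstrap bootstrap replicates (0 gives the point estimate
#'   only).
#' @param seed bootstrap seed.
#' @return An `icer_result` with `delta_cost`, `delta_effect`, their
#'   variances, the ratio, classification and Fieller limits.
#' @export
icer_within_trial <- function(records, arm = "mms", ref = "control",
                              discount_rate = 0.015, horizon = NULL,
                              alpha = 0.05, n_bootstrap = 200, seed = 1L) {
  sub_a <- select_arm(records, arm)
  sub_b <- select_arm(records, ref)
  if (is.null(horizon))
    horizon <- min(max(sub_a$followup_time), max(sub_b$followup_time))
  stats_a <- arm_cost_effect(sub_a, discount_rate, horizon, n_bootstrap,
                             seed)
  stats_b <- arm_cost_effect(sub_b, discount_rate, horizon, n_bootstrap,
                             seed + 1L)
  dc <- stats_a$cost - stats_b$cost
  de <- stats_a$effect - stats_b$effect
  res <- compute_icer(dc, de)
  res$horizon <- horizon
  res$discount_rate <- discount_rate
  if (n_bootstrap > 0) {
    vc <- stats_a$var_cost + stats_b$var_cost
    ve <- stats_a$var_effect + stats_b$var_effect
    cv <- stats_a$cov + stats_b$cov
    ci <- fieller_ci(dc, de, vc, ve, cv, alpha)
    res$var_cost <- vc
    res$var_effect <- ve
    res$covariance <- cv
    res$ci_low <- ci$lower
    res$ci_high <- ci$upper
    res$bounded <- ci$bounded
    res$alpha <- alpha
  }
  res
}

# Point estimates plus joint bootstrap moments of (mean cost, RMST) for one
# arm's records.
arm_cost_effect <- function(sub, rate, horizon, n_bootstrap, seed) {
  t <- sub$followup_time
  ev <- sub$event
  cmat <- cost_matrix(sub)
  cost <- lin_point_estimate(t, ev, cmat, rate)$mean
  km <- km_estimate(sub)
  effect <- restricted_mean(km, min(horizon, km$max_time), rate)$estimate
  out <- list(cost = cost, effect = effect, var_cost = 0, var_effect = 0,
              cov = 0)
  if (n_bootstrap > 0) {
    set.seed(seed)
    n <- nrow(sub)
    reps <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tb <- t[idx]
      eb <- ev[idx]
      cb <- lin_point_estimate(tb, eb, cmat[idx, , drop = FALSE], rate)$mean
      fit <- survival::survfit(survival::Surv(tb, eb) ~ 1,
                               conf.type = "none")
      keep <- fit$n.event > 0
      effb <- step_discounted_integral(fit$time[keep], fit$surv[keep],
                                       min(horizon, max(tb)), rate)
      c(cb, effb)
    }, numeric(2))
    out$var_cost <- var(reps[1, ])
    out$var_effect <- var(reps[2, ])
    out$cov <- cov(reps[1, ], reps[2, ])
  }
  out
}

#' Univariate sensitivity sweep over the screening test cost
#'
#' Re-runs the within-trial cost estimation and ICER with the per-screen
#' test cost (CA125 plus risk algorithm) replaced by each candidate value,
#' all other parameters and the random seed held fixed -- so the simulated
#' event histories are identical across the sweep and only costs move.
#'
#' @param design,hazard,costs,seed trial generator inputs (see
#'   [generate_trial()]).
#' @param test_costs candidate per-test costs in pounds.
#' @param discount_rate annual discount rate.
#' @param arm,ref compared arms.
#' @param alpha,n_bootstrap,boot_seed Fieller interval settings (bootstrap
#'   skipped when `n_bootstrap = 0`).
#' @return Data frame with one row per test cost: `test_cost`,
#'   `delta_cost`, `delta_effect`, `icer`, `classification` (and Fieller
#'   limits when bootstrapped).
#' @export
univariate_sweep <- function(design, hazard, costs, test_costs,
                             discount_rate = 0.015, seed = 1L,
                             arm = "mms", ref = "control", alpha = 0.05,
                             n_bootstrap = 0, boot_seed = 1L) {
  if (length(test_costs) == 0) stop("'test_costs' is empty", call. = FALSE)
  if (any(test_costs < 0)) stop("negative test cost", call. = FALSE)
  rows <- lapply(test_costs, function(tc) {
    cc <- costs
    cc$test_cost <- tc
    tr <- generate_trial(design, hazard, cc, seed)
    res <- icer_within_trial(tr, arm = arm, ref = ref,
                             discount_rate = discount_rate, alpha = alpha,
                             n_bootstrap = n_bootstrap, seed = boot_seed)
    data.frame(test_cost = tc, delta_cost = res$delta_cost,
               delta_effect = res$delta_effect, icer = res$ratio,
               classification = res$classification,
               ci_low = res$ci_low, ci_high = res$ci_high)
  })
  do.call(rbind, rows)
}
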