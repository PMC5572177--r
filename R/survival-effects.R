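# Kaplan-Meier survival and discounted restricted mean survival time.

#' Kaplan-Meier curve for time to ovarian-cancer death
#'
#' Product-limit estimate of the survival function for one trial arm,
#' treating `event == 1` as the event and `event == 0` as right-censoring
#' (deaths are processed before censorings at tied times, the standard
#' convention). Estimation is delegated to [survival::survfit()];
#' Greenwood variances are retained.
#'
#' @param records patient records (see [generate_trial()]).
#' @param arm arm label; `NULL` uses all rows.
#' @return An object of class `km_curve`: event times, survival estimates,
#'   risk-set and event counts, Greenwood standard errors, sample size and
#'   the largest observed (event or censoring) time.
#' @examples
#' tr <- generate_trial(trial_design(500, 250, 250), hazard_spec(),
#'                      cost_model(), seed = 1)
#' km <- km_estimate(tr, "control")
#' @export
km_estimate <- function(records, arm = NULL) {
  sub <- select_arm(records, arm)
  if (any(sub$followup_time <= 0))
    stop("follow-up times must be positive", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(sub$followup_time, sub$event) ~ 1, conf.type = "none")
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 std_err = fit$std.err[keep] * fit$surv[keep],
                 n = nrow(sub), max_time = max(sub$followup_time),
                 arm = if (is.null(arm)) "all" else arm),
            class = "km_curve")
}

select_arm <- function(records, arm) {
  stopifnot(is.data.frame(records))
  if (is.null(arm)) sub <- records
  else {
    arm <- match.arg(arm, c("control", "mms", "uss"))
    sub <- records[records$arm == arm, , drop = FALSE]
  }
  if (nrow(sub) == 0L) stop("no records in arm", call. = FALSE)
  sub
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve (%s): n = %d, %d deaths, max time %.3f y\n",
              x$arm, x$n, sum(x$n_event), x$max_time))
  if (length(x$times))
    cat(sprintf("  final survival %.5f\n", min(x$survival)))
  invisible(x)
}

#' Discounted restricted mean survival time
#'
#' Area under the Kaplan-Meier step curve up to `horizon`, with each
#' follow-up year's contribution discounted by \eqn{(1+\delta)^{-k}} (year
#' 0 undiscounted):
#' \deqn{\hat\mu = \sum_{k \ge 0} (1+\delta)^{-k}
#'       \int_k^{\min(k+1,\tau)} \hat S(t)\,dt.}
#' With `discount_rate = 0` this is the ordinary restricted mean survival
#' time. The standard error generalises the usual RMST variance: with
#' \eqn{A(t) = \int_t^\tau w(u)\hat S(u)\,du} the discount-weighted
#' residual area,
#' \deqn{\widehat{Var} = \sum_{t_i \le \tau} A(t_i)^2
#'       \frac{d_i}{n_i (n_i - d_i)}.}
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param horizon restriction time \eqn{\tau}; defaults to the largest
#'   observed time. Requesting a horizon beyond follow-up is an error (no
#'   silent extrapolation).
#' @param discount_rate annual discount rate \eqn{\delta}.
#' @return An object of class `rmst_result` with fields `estimate`,
#'   `std_error`, `horizon`, `discount_rate`, `n`.
#' @examples
#' tr <- generate_trial(trial_design(500, 250, 250), hazard_spec(),
#'                      cost_model(), seed = 1)
#' restricted_mean(km_estimate(tr, "control"), discount_rate = 0.015)
#' @export
restricted_mean <- function(curve, horizon = NULL, discount_rate = 0) {
  stopifnot(inherits(curve, "km_curve"))
  if (is.null(horizon)) horizon <- curve$max_time
  stop_if_not_scalar(horizon, "horizon")
  stop_if_not_scalar(discount_rate, "discount_rate", lower = 0)
  if (horizon <= 0) stop("'horizon' must be positive", call. = FALSE)
  if (horizon > curve$max_time + 1e-9)
    stop(sprintf(
      "horizon %.4f exceeds maximum observed time %.4f: refusing to extrapolate",
      horizon, curve$max_time), call. = FALSE)
  est <- step_discounted_integral(curve$times, curve$survival,
                                  horizon, discount_rate)
  keep <- curve$times <= horizon & curve$n_event > 0
  v <- 0
  if (any(keep)) {
    ti <- curve$times[keep]
    resid_area <- vapply(ti, function(t0) {
      discounted_area_from(curve, t0, horizon, discount_rate)
    }, numeric(1))
    di <- curve$n_event[keep]
    ni <- curve$at_risk[keep]
    term <- ifelse(ni - di > 0, di / (ni * (ni - di)), 0)
    v <- sum(resid_area^2 * term)
  }
  structure(list(estimate = est, std_error = sqrt(v), horizon = horizon,
                 discount_rate = discount_rate, n = curve$n,
                 arm = curve$arm),
            class = "rmst_result")
}

# Discount-weighted area under the KM step curve on [t0, tau].
discounted_area_from <- function(curve, t0, tau, rate) {
  if (t0 >= tau) return(0)
  full <- step_discounted_integral(curve$times, curve$survival, tau, rate)
  if (t0 <= 0) return(full)
  full - step_discounted_integral(curve$times, curve$survival, t0, rate)
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf(
    "Restricted mean survival (%s): %.5f y (se %.5f) to %.4f y, discount %.1f%%\n",
    x$arm, x$estimate, x$std_error, x$horizon, 100 * x$discount_rate))
  invisible(x)
}

#' Difference in restricted mean survival between two arms
#'
#' @param a,b `rmst_result` objects sharing horizon and discount rate;
#'   arms are independent so variances add.
#' @return A list with `difference` (years), `variance`, `std_error`,
#'   `horizon` and `discount_rate`.
#' @examples
#' a <- structure(list(estimate = 12.36845, std_error = 0.0017,
#'                     horizon = 13.5574, discount_rate = 0.015, n = 50624),
#'                class = "rmst_result")
#' b <- structure(list(estimate = 12.36565, std_error = 0.0012,
#'                     horizon = 13.5574, discount_rate = 0.015, n = 101299),
#'                class = "rmst_result")
#' effect_difference(a, b)$difference  # 0.0028
#' @export
effect_difference <- function(a, b) {
  stopifnot(inherits(a, "rmst_result"), inherits(b, "rmst_result"))
  if (abs(a$horizon - b$horizon) > 1e-9)
    stop("restricted means have different horizons", call. = FALSE)
  if (abs(a$discount_rate - b$discount_rate) > 1e-12)
    stop("restricted means have different discount rates", call. = FALSE)
  v <- a$std_error^2 + b$std_error^2
  list(difference = a$estimate - b$estimate, variance = v,
       std_error = sqrt(v), horizon = a$horizon,
       discount_rate = a$discount_rate)
}

#' Per-arm restricted-mean survival table
#'
#' Computes the discounted restricted mean survival for each arm at each
#' discount rate, restricting at the pooled maximum observed time (all arms
#' share one horizon).
#'
#' @param records patient records.
#' @param discount_rates numeric vector of annual discount rates.
#' @param horizon restriction time shared by all arms; the default is the
#'   largest time at which every arm's curve is still defined (the pooled
#'   maximum, capped so no arm is extrapolated).
#' @return A data frame with columns `arm`, `discount_rate`, `mean`, `se`,
#'   `horizon`.
#' @export
rmst_table <- function(records, discount_rates = c(0, 0.015, 0.035),
                       horizon = NULL) {
  arms <- intersect(c("control", "mms", "uss"), unique(records$arm))
  kms <- lapply(arms, function(a) km_estimate(records, a))
  names(kms) <- arms
  common_max <- min(vapply(kms, function(k) k$max_time, numeric(1)))
  if (is.null(horizon)) horizon <- common_max
  horizon <- min(horizon, common_max)
  rows <- list()
  for (a in arms) {
    km <- kms[[a]]
    for (d in discount_rates) {
      r <- restricted_mean(km, horizon = horizon, discount_rate = d)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = a, discount_rate = d, mean = r$estimate, se = r$std_error,
        horizon = r$horizon)
    }
  }
  do.call(rbind, rows)
}
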