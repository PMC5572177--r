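# 25-year extrapolation of life-years and costs beyond the trial horizon.
#
# Life-years: hybrid estimate -- Kaplan-Meier discounted restricted mean
# within the trial, grafted onto the Royston-Parmar conditional survival
# beyond it. Costs: two-component yearly sums (expected survivors at the
# survivor annual cost, expected decedents at the decedent annual cost),
# both weighted by parametric survival. No competing-risk adjustment is
# applied here; the Markov module handles competing mortality instead.

#' Extrapolated discounted life-year difference between two arms
#'
#' Per arm, discounted life-years to `horizon` are the within-trial
#' discounted restricted mean (Kaplan-Meier, up to `trial_end`) plus the
#' post-trial integral of the grafted parametric survival
#' \eqn{\hat S_{KM}(\tau_0)\, S_m(t) / S_m(\tau_0)} with the same annual
#' discount weights. Grafting keeps the within-trial results nonparametric
#' (an all-parametric mode is available via `hybrid = FALSE`).
#'
#' @param model_a,model_b fitted [fit_rp_model()] objects for the two arms.
#' @param km_a,km_b the corresponding `km_curve`s.
#' @param horizon extrapolation horizon in years (default 25); must exceed
#'   `trial_end`.
#' @param discount_rate annual discount rate.
#' @param trial_end end of within-trial follow-up; default the larger time
#'   both curves support.
#' @param hybrid if `TRUE` (default) use KM within trial and the grafted
#'   spline beyond; if `FALSE` use the parametric survival throughout.
#' @return A list: `delta` (arm a minus arm b, discounted years), per-arm
#'   totals `ly_a`/`ly_b`, their within-trial parts, and a per-year
#'   survival table.
#' @export
extrapolate_effects <- function(model_a, model_b, km_a, km_b, horizon = 25,
                                discount_rate = 0.015, trial_end = NULL,
                                hybrid = TRUE) {
  stopifnot(inherits(model_a, "rp_model"), inherits(model_b, "rp_model"),
            inherits(km_a, "km_curve"), inherits(km_b, "km_curve"))
  if (is.null(trial_end)) trial_end <- min(km_a$max_time, km_b$max_time)
  if (horizon <= trial_end)
    stop("'horizon' must exceed the trial follow-up", call. = FALSE)
  one_arm <- function(model, km) {
    if (hybrid) {
      within <- restricted_mean(km, trial_end, discount_rate)$estimate
      anchor <- km_survival_at(km, trial_end)
      sfun <- function(t) anchor * rp_survival(model, t) /
        rp_survival(model, trial_end)
    } else {
      within <- discounted_parametric_area(model, 0, trial_end,
                                           discount_rate)
      sfun <- function(t) rp_survival(model, t)
    }
    post <- discounted_area(sfun, trial_end, horizon, discount_rate)
    list(total = within + post, within = within)
  }
  a <- one_arm(model_a, km_a)
  b <- one_arm(model_b, km_b)
  yrs <- seq(ceiling(trial_end), horizon)
  surv_tab <- data.frame(
    year = yrs,
    survival_a = rp_survival(model_a, yrs),
    survival_b = rp_survival(model_b, yrs))
  list(delta = a$total - b$total, ly_a = a$total, ly_b = b$total,
       within_a = a$within, within_b = b$within, trial_end = trial_end,
       horizon = horizon, discount_rate = discount_rate,
       survival = surv_tab)
}

km_survival_at <- function(km, t0) {
  if (length(km$times) == 0) return(1)
  sf <- stepfun(km$times, c(1, km$survival), right = FALSE)
  sf(t0)
}

# \int_a^b w(floor(t)) s(t) dt with yearly discount weights, by adaptive
# quadrature on each year segment.
discounted_area <- function(sfun, a, b, rate) {
  marks <- if (ceiling(a) <= floor(b)) seq(ceiling(a), floor(b)) else numeric()
  cuts <- sort(unique(c(a, marks, b)))
  cuts <- cuts[cuts >= a & cuts <= b]
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    lo <- cuts[i]
    hi <- cuts[i + 1]
    if (hi - lo < 1e-12) next
    w <- discount_weight(floor(lo + 1e-9), rate)
    total <- total + w * integrate(sfun, lo, hi, rel.tol = 1e-10)$value
  }
  total
}

discounted_parametric_area <- function(model, a, b, rate) {
  discounted_area(function(t) rp_survival(model, t), a, b, rate)
}

#' Extrapolated discounted cost beyond the trial
#'
#' Two-component yearly cost sum over the extrapolation period:
#' \deqn{\sum_{k} (1+\delta)^{-k} [S(k+1)\, c_{surv} +
#'       (S(k) - S(k+1))\, c_{dec}],}
#' summing over whole years `k` from `ceiling(trial_end)` to
#' `horizon - 1`: expected survivors of each year accrue the survivor
#' annual cost, expected decedents the decedent annual cost. Survival comes
#' from the parametric model, optionally grafted at `trial_end` onto a
#' within-trial anchor (`anchor_survival`). Costs are assumed to continue
#' on their within-trial pattern (screening, testing, treatment) to the end
#' of the extrapolation period.
#'
#' @param model an `rp_model`.
#' @param survivor_cost,decedent_cost annual cost (pounds) for a woman
#'   surviving the year / dying in the year; see
#'   [annual_cost_components()].
#' @param trial_end,horizon extrapolation window in years.
#' @param discount_rate annual discount rate.
#' @param anchor_survival optional survival level at `trial_end` (e.g. the
#'   Kaplan-Meier estimate); if supplied, post-trial survival is
#'   `anchor_survival * S(t)/S(trial_end)`.
#' @return Discounted extrapolated cost in pounds.
#' @export
extrapolate_costs <- function(model, survivor_cost, decedent_cost,
                              trial_end, horizon, discount_rate = 0.015,
                              anchor_survival = NULL) {
  stop_if_not_scalar(survivor_cost, "survivor_cost", lower = 0)
  stop_if_not_scalar(decedent_cost, "decedent_cost", lower = 0)
  if (horizon <= trial_end)
    stop("'horizon' must exceed 'trial_end'", call. = FALSE)
  if (ceiling(trial_end) > horizon - 1) return(0)
  yrs <- seq(ceiling(trial_end), horizon - 1)
  s <- rp_survival(model, c(yrs, horizon))
  if (!is.null(anchor_survival))
    s <- anchor_survival * s / rp_survival(model, trial_end)
  if (any(diff(s) > 1e-10))
    stop("survival non-monotone over the extrapolation period",
         call. = FALSE)
  s_start <- s[seq_along(yrs)]
  s_end <- s[seq_along(yrs) + 1L]
  sum(discount_weight(yrs, discount_rate) *
        (s_end * survivor_cost + (s_start - s_end) * decedent_cost))
}

#' Within-trial annual cost of survivors and decedents
#'
#' Estimates the two cost components the extrapolation assumes persist
#' beyond the trial: the mean observed annual cost among person-years whose
#' interval was survived, and among person-years in which the woman died.
#'
#' @param records patient records.
#' @param arm arm label.
#' @return List with `survivor_cost`, `decedent_cost` (pounds per year) and
#'   the person-year counts behind each.
#' @export
annual_cost_components <- function(records, arm = NULL) {
  sub <- select_arm(records, arm)
  cmat <- cost_matrix(sub)
  t <- sub$followup_time
  ev <- sub$event
  surv_sum <- 0; surv_n <- 0; dec_sum <- 0; dec_n <- 0
  for (k in seq_len(ncol(cmat)) - 1L) {
    survived <- t >= k + 1
    died <- ev == 1L & t > k & t <= k + 1
    surv_sum <- surv_sum + sum(cmat[survived, k + 1L])
    surv_n <- surv_n + sum(survived)
    dec_sum <- dec_sum + sum(cmat[died, k + 1L])
    dec_n <- dec_n + sum(died)
  }
  list(survivor_cost = if (surv_n > 0) surv_sum / surv_n else 0,
       decedent_cost = if (dec_n > 0) dec_sum / dec_n else 0,
       survivor_years = surv_n, decedent_years = dec_n)
}

#' Extrapolated ICER from patient-level records
#'
#' Full extrapolation pipeline for one comparison: Royston-Parmar models
#' per arm selected by AIC, hybrid discounted life-years to `horizon`,
#' within-trial censoring-adjusted costs plus two-component extrapolated
#' costs, and the resulting ICER.
#'
#' @param records patient records.
#' @param arm,ref compared arms.
#' @param horizon extrapolation horizon (years).
#' @param discount_rate annual discount rate.
#' @param df_grid spline complexities for AIC selection.
#' @return A list with the selected models, `delta_lyg`, `delta_cost`
#'   (within + extrapolated), their within-trial parts and the `icer`.
#' @export
extrapolate_icer <- function(records, arm = "mms", ref = "control",
                             horizon = 25, discount_rate = 0.015,
                             df_grid = 1:3) {
  sub_a <- select_arm(records, arm)
  sub_b <- select_arm(records, ref)
  km_a <- km_estimate(sub_a)
  km_b <- km_estimate(sub_b)
  trial_end <- min(km_a$max_time, km_b$max_time)
  mod_a <- select_by_aic(sub_a, df_grid = df_grid)
  mod_b <- select_by_aic(sub_b, df_grid = df_grid)
  eff <- extrapolate_effects(mod_a, mod_b, km_a, km_b, horizon,
                             discount_rate, trial_end)
  cost_a_wt <- lin_point_estimate(sub_a$followup_time, sub_a$event,
                                  cost_matrix(sub_a), discount_rate)$mean
  cost_b_wt <- lin_point_estimate(sub_b$followup_time, sub_b$event,
                                  cost_matrix(sub_b), discount_rate)$mean
  cc_a <- annual_cost_components(sub_a)
  cc_b <- annual_cost_components(sub_b)
  ext_a <- extrapolate_costs(mod_a, cc_a$survivor_cost, cc_a$decedent_cost,
                             trial_end, horizon, discount_rate,
                             anchor_survival = km_survival_at(km_a,
                                                              trial_end))
  ext_b <- extrapolate_costs(mod_b, cc_b$survivor_cost, cc_b$decedent_cost,
                             trial_end, horizon, discount_rate,
                             anchor_survival = km_survival_at(km_b,
                                                              trial_end))
  delta_cost <- (cost_a_wt + ext_a) - (cost_b_wt + ext_b)
  res <- compute_icer(delta_cost, eff$delta)
  list(model_a = mod_a, model_b = mod_b, delta_lyg = eff$delta,
       delta_cost = delta_cost,
       within_delta_cost = cost_a_wt - cost_b_wt,
       within_delta_effect = eff$within_a - eff$within_b,
       cost_components = list(a = cc_a, b = cc_b),
       icer = res$ratio, classification = res$classification,
       horizon = horizon, discount_rate = discount_rate,
       trial_end = trial_end, effects = eff)
}
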