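# Synthetic patient-level trial generator and its closed-form oracle.

arm_seed <- function(seed, arm) {
  offs <- c(control = 0L, mms = 1L, uss = 2L)[[arm]]
  as.integer((as.numeric(seed) + offs * 1000003) %% 2147483647)
}

#' Generate a synthetic screening trial
#'
#' Simulates patient-level records for a three-arm ovarian-cancer screening
#' trial: ovarian-cancer death times from the piecewise-exponential hazard
#' in `hazard` (baseline before the lead time; reduced after it in the
#' screened arms), administrative censoring at an entry-dependent follow-up
#' between `max_followup - recruitment_window` and `max_followup` years, and
#' yearly cost accrual (per-screen test costs plus Bernoulli referral scans
#' while alive, on-screen and undiagnosed; one stage-specific treatment
#' cost in the diagnosis year, which precedes an ovarian-cancer death by
#' `costs$diagnosis_lead` years).
#'
#' Each arm draws from its own random stream derived from `seed`, so
#' changing one arm's size leaves the other arms' records untouched.
#' Identical inputs give identical output.
#'
#' @param design a [trial_design()].
#' @param hazard a [hazard_spec()].
#' @param costs a [cost_model()].
#' @param seed integer master seed.
#' @return A `data.frame` (class `oc_trial`) with one row per woman:
#'   `id`, `arm` (`control`/`mms`/`uss`), `followup_time` (years),
#'   `event` (1 = ovarian-cancer death), `diagnosis_year` (0-indexed year or
#'   `NA`), `stage` (`early`/`advanced`/`NA`) and yearly cost columns
#'   `cost_y0`, `cost_y1`, ... (zero beyond each woman's follow-up).
#' @examples
#' tr <- generate_trial(trial_design(2000, 1000, 1000), hazard_spec(),
#'                      cost_model(), seed = 1)
#' table(tr$arm, tr$event)
#' @export
generate_trial <- function(design, hazard, costs, seed) {
  stopifnot(inherits(design, "trial_design"), inherits(hazard, "hazard_spec"),
            inherits(costs, "cost_model"))
  stop_if_not_scalar(seed, "seed")
  k_years <- ceiling(design$max_followup)
  arms <- list(
    control = list(n = design$n_control, prefix = "C", screened = FALSE),
    mms = list(n = design$n_mms, prefix = "M", screened = TRUE,
               screen_cost = costs$test_cost + costs$phlebotomy_cost,
               early_frac = costs$early_fraction_screened),
    uss = list(n = design$n_uss, prefix = "U", screened = TRUE,
               screen_cost = costs$tvs_cost,
               early_frac = costs$early_fraction_screened))
  arms$control$early_frac <- costs$early_fraction_control
  out <- lapply(names(arms), function(a) {
    generate_arm(a, arms[[a]], design, hazard, costs,
                 arm_seed(seed, a), k_years)
  })
  res <- data.table::rbindlist(out)
  res <- as.data.frame(res)
  res$arm <- factor(res$arm, levels = c("control", "mms", "uss"))
  attr(res, "design") <- design
  attr(res, "hazard") <- hazard
  attr(res, "costs") <- costs
  attr(res, "seed") <- seed
  class(res) <- c("oc_trial", class(res))
  res
}

generate_arm <- function(arm, info, design, hazard, costs, seed, k_years) {
  n <- info$n
  set.seed(seed)
  # Event-time draws come first so that cost parameters never perturb them.
  e_oc <- rexp(n)
  offset <- runif(n, 0, max(design$recruitment_window, 0))
  e_other <- rexp(n)
  u_stage <- runif(n)

  hz <- arm_hazard_rates(hazard, arm)
  lead <- hz$breaks
  h_lead <- hz$rates[1] * lead
  t_oc <- ifelse(e_oc < h_lead, e_oc / hz$rates[1],
                 lead + (e_oc - h_lead) / hz$rates[2])
  t_oc[is.nan(t_oc)] <- Inf # both rates zero
  censor <- design$max_followup - offset
  t_other <- if (hazard$other_cause_hazard > 0)
    e_other / hazard$other_cause_hazard else rep(Inf, n)

  followup <- pmin(t_oc, censor, t_other)
  event <- as.integer(t_oc <= pmin(censor, t_other))

  # fatal cancers are diagnosed `diagnosis_lead` years before death; a
  # diagnosis inside follow-up is recorded (with its treatment cost) even
  # when the death itself falls beyond censoring
  t_dx <- pmax(t_oc - costs$diagnosis_lead, 0)
  diagnosed <- is.finite(t_dx) & t_dx < followup
  dx_year <- ifelse(diagnosed, floor(t_dx), NA_real_)
  stage <- ifelse(diagnosed,
                  ifelse(u_stage < info$early_frac, "early", "advanced"),
                  NA_character_)

  cost <- matrix(0, nrow = n, ncol = k_years)
  if (isTRUE(info$screened)) {
    n_screens <- pmax(0, floor(design$screening_duration - offset))
    u_ref <- matrix(runif(n * k_years), nrow = n)
    for (k in seq_len(k_years) - 1L) {
      on_screen <- (k < n_screens) & (k < followup) & (k < t_dx)
      ref <- on_screen & (u_ref[, k + 1L] < costs$referral_fraction)
      cost[, k + 1L] <- on_screen * info$screen_cost + ref * costs$tvs_cost
    }
  }
  dx <- which(diagnosed)
  if (length(dx)) {
    treat <- ifelse(stage[dx] == "early", costs$early_treatment_cost,
                    costs$advanced_treatment_cost)
    cost[cbind(dx, dx_year[dx] + 1L)] <-
      cost[cbind(dx, dx_year[dx] + 1L)] + treat
  }
  colnames(cost) <- paste0("cost_y", seq_len(k_years) - 1L)
  data.table::data.table(
    id = sprintf("%s%06d", info$prefix, seq_len(n)),
    arm = arm, followup_time = followup, event = event,
    diagnosis_year = as.integer(dx_year), stage = stage, cost)
}

cost_columns <- function(records) {
  grep("^cost_y\\d+$", names(records), value = TRUE)
}

cost_matrix <- function(records) {
  cols <- cost_columns(records)
  m <- as.matrix(records[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Exact discounted restricted mean survival under the generating model
#'
#' Closed-form discounted restricted mean of the time-to-ovarian-cancer-death
#' distribution implied by a [hazard_spec()] for one arm: the
#' piecewise-exponential survival curve is integrated year by year with the
#' package's annual discount weights \eqn{(1+\delta)^{-k}} (year 0
#' undiscounted). Serves as the analytic oracle against which Kaplan-Meier
#' restricted means on generated data are checked.
#'
#' @param hazard a [hazard_spec()].
#' @param arm `"control"`, `"mms"` or `"uss"`.
#' @param horizon restriction time \eqn{\tau} in years.
#' @param discount_rate annual discount rate \eqn{\delta} (proportion).
#' @return Discounted restricted mean survival in years.
#' @examples
#' true_rmst(hazard_spec(baseline_oc_hazard = 0), "control", 10, 0)  # 10
#' @export
true_rmst <- function(hazard, arm, horizon, discount_rate = 0) {
  stopifnot(inherits(hazard, "hazard_spec"))
  stop_if_not_scalar(horizon, "horizon")
  if (horizon <= 0) stop("'horizon' must be positive", call. = FALSE)
  stop_if_not_scalar(discount_rate, "discount_rate", lower = 0)
  hz <- arm_hazard_rates(hazard, arm)
  rate_at <- function(t) ifelse(t < hz$breaks, hz$rates[1], hz$rates[2])
  cumhaz <- function(t) hz$rates[1] * pmin(t, hz$breaks) +
    hz$rates[2] * pmax(t - hz$breaks, 0)
  cuts <- sort(unique(c(0, seq_len(ceiling(horizon)) - 1,
                        hz$breaks[hz$breaks < horizon], horizon)))
  cuts <- cuts[cuts >= 0 & cuts <= horizon]
  a <- cuts[-length(cuts)]
  b <- cuts[-1]
  s_a <- exp(-cumhaz(a))
  r <- rate_at(a)
  seg <- ifelse(r > 0, s_a * (1 - exp(-r * (b - a))) / r, s_a * (b - a))
  sum(discount_weight(floor(a + 1e-12), discount_rate) * seg)
}

#' Write or read patient records as CSV
#'
#' Plain-text interchange format for simulated (or external) patient
#' records: header `id,arm,followup_time,event,diagnosis_year,stage,
#' cost_y0,cost_y1,...`, with yearly cost columns padded with zeros beyond
#' each woman's follow-up.
#'
#' @param records an `oc_trial` data frame (or any data frame with the
#'   columns above).
#' @param path file path.
#' @return `read_trial` returns the records as a data frame of class
#'   `oc_trial`; `write_trial` returns `path` invisibly.
#' @export
write_trial <- function(records, path) {
  data.table::fwrite(as.data.frame(records), path)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  res <- as.data.frame(data.table::fread(path))
  needed <- c("id", "arm", "followup_time", "event")
  if (!all(needed %in% names(res)))
    stop("patient CSV must contain columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  res$arm <- factor(res$arm, levels = c("control", "mms", "uss"))
  if (!"stage" %in% names(res)) res$stage <- NA_character_
  class(res) <- c("oc_trial", class(res))
  res
}
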