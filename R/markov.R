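# Annual-cycle Markov cohort model: well -> {benign oophorectomy,
# early ovarian cancer, advanced ovarian cancer} with ovarian-cancer death,
# life-table competing mortality in every alive state, QALYs and costs.

#' Convert an annual hazard rate to a transition probability
#'
#' @param rate annual hazard (per year), non-negative.
#' @return \eqn{1 - e^{-rate}}.
#' @examples
#' hazard_to_probability(log(2))  # 0.5
#' @export
hazard_to_probability <- function(rate) {
  if (any(!is.numeric(rate)) || any(is.na(rate)) || any(rate < 0))
    stop("'rate' must be non-negative", call. = FALSE)
  1 - exp(-rate)
}

#' Markov model specification for one screening strategy
#'
#' States: `well`, `benign_ooph` (a one-cycle tunnel for benign
#' oophorectomy, returning to `well`), `early_oc` and `advanced_oc`
#' (persistent until death), `oc_death` and `other_death` (absorbing).
#' Life-table competing mortality applies in every alive state. Annual
#' transition probabilities out of `well` are `p_benign` and the cancer
#' incidence split by `early_fraction`; cancer states progress to
#' `oc_death` with `p_early_death` / `p_adv_death` per cycle.
#'
#' Costs: under screening, every well-year incurs the screen cost
#' (test + phlebotomy + outpatient visit); entering `benign_ooph` incurs
#' the surgery-plus-follow-up cost once; entering a cancer state incurs the
#' stage-specific weighted treatment cost once (these are per-case, not
#' per-year, costs). Utilities weight each state-year; `well` and
#' `benign_ooph` default to 1 (unstated in source tariffs), cancer states
#' to the stable/progressive disease tariffs 0.718 and 0.649.
#'
#' Default transition inputs are the package's calibration to the emulated
#' trial's structure (screening shifts diagnoses toward early stage and
#' adds benign surgery); all are overridable.
#'
#' @param strategy `"screening"` or `"no_screening"`.
#' @param start_age cohort age at cycle 0.
#' @param discount_rate annual discount rate (cycle 0 undiscounted).
#' @param test_cost,phlebotomy_cost,outpatient_cost per-screen cost
#'   components charged per well-year under screening.
#' @param benign_cost one-off cost of benign oophorectomy plus follow-up
#'   visit.
#' @param early_cost,advanced_cost one-off weighted treatment cost on entry
#'   to a cancer state.
#' @param utilities named vector with entries `well`, `benign_ooph`,
#'   `early_oc`, `advanced_oc` in `[0, 1]`.
#' @param p_benign annual probability of benign oophorectomy from `well`.
#' @param incidence annual ovarian-cancer incidence from `well`.
#' @param early_fraction fraction of incident cancers diagnosed early.
#' @param p_early_death,p_adv_death annual ovarian-cancer death probability
#'   from each cancer state.
#' @param screening_stop_age age after which screening costs stop
#'   (`Inf` = costs continue for life, the default assumption).
#' @return An object of class `markov_spec`.
#' @examples
#' markov_spec("screening")
#' @export
markov_spec <- function(strategy = c("screening", "no_screening"),
                        start_age = 60, discount_rate = 0.015,
                        test_cost = 20, phlebotomy_cost = 3,
                        outpatient_cost = 109,
                        benign_cost = 2275 + 139,
                        early_cost = 3422, advanced_cost = 5666,
                        utilities = c(well = 1, benign_ooph = 1,
                                      early_oc = 0.718,
                                      advanced_oc = 0.649),
                        p_benign = NULL, incidence = 6e-4,
                        early_fraction = NULL,
                        p_early_death = 0.02, p_adv_death = 0.30,
                        screening_stop_age = Inf) {
  strategy <- match.arg(strategy)
  screening <- strategy == "screening"
  if (is.null(p_benign)) p_benign <- if (screening) 0.0014 else 0.0003
  if (is.null(early_fraction))
    early_fraction <- if (screening) 0.45 else 0.25
  for (nm in c("test_cost", "phlebotomy_cost", "outpatient_cost",
               "benign_cost", "early_cost", "advanced_cost"))
    stop_if_not_scalar(get(nm), nm, lower = 0)
  for (nm in c("p_benign", "incidence", "early_fraction", "p_early_death",
               "p_adv_death"))
    stop_if_not_scalar(get(nm), nm, lower = 0, upper = 1)
  stop_if_not_scalar(discount_rate, "discount_rate", lower = 0)
  need <- c("well", "benign_ooph", "early_oc", "advanced_oc")
  if (!all(need %in% names(utilities)) ||
      any(utilities[need] < 0 | utilities[need] > 1))
    stop("'utilities' must name well, benign_ooph, early_oc, advanced_oc ",
         "with values in [0, 1]", call. = FALSE)
  structure(list(strategy = strategy, screening = screening,
                 start_age = start_age, discount_rate = discount_rate,
                 screen_cost = if (screening)
                   test_cost + phlebotomy_cost + outpatient_cost else 0,
                 test_cost = test_cost, phlebotomy_cost = phlebotomy_cost,
                 outpatient_cost = outpatient_cost,
                 benign_cost = benign_cost, early_cost = early_cost,
                 advanced_cost = advanced_cost,
                 utilities = utilities[need],
                 p_benign = p_benign, incidence = incidence,
                 early_fraction = early_fraction,
                 p_early_death = p_early_death,
                 p_adv_death = p_adv_death,
                 screening_stop_age = screening_stop_age),
            class = "markov_spec")
}

markov_states <- c("well", "benign_ooph", "early_oc", "advanced_oc",
                   "oc_death", "other_death")

#' Run the Markov cohort for one strategy
#'
#' Cycles the cohort annually from `start_age` with everyone `well`.
#' Competing other-cause death is applied from the life table at the
#' cohort's current age in every alive state. Life-years, QALYs and costs
#' accrue on state-at-cycle-start occupancy with annual discount weights
#' (cycle 0 undiscounted); one-off entry costs are charged in the arrival
#' cycle. Cycling stops when alive occupancy falls below `tol` or the life
#' table is exhausted (its final age has `qx = 1`).
#'
#' @param spec a [markov_spec()].
#' @param life_table a life table covering `start_age` onwards.
#' @param tol alive-occupancy threshold for stopping.
#' @param half_cycle if `TRUE`, accrue life-years/QALYs/state costs on the
#'   average of start- and end-of-cycle occupancy.
#' @return A list of class `cohort_trace`: `trace` (occupancy per cycle),
#'   `life_years`, `qalys`, `cost` (all discounted), `cycles`.
#' @examples
#' run_cohort(markov_spec("no_screening", incidence = 0, p_benign = 0),
#'            gompertz_life_table())
#' @export
run_cohort <- function(spec, life_table, tol = 1e-9, half_cycle = FALSE) {
  stopifnot(inherits(spec, "markov_spec"))
  ages <- seq(spec$start_age, max(life_table$age))
  if (!spec$start_age %in% life_table$age)
    stop("life table does not cover the start age", call. = FALSE)
  # validate probability budgets before simulating; competing other-cause
  # death is applied first each cycle and disease transitions act on the
  # survivors, so each budget must be a probability on its own
  inc <- spec$incidence
  if (spec$p_benign + inc > 1)
    stop("well-state outgoing probabilities exceed 1", call. = FALSE)
  if (spec$p_early_death > 1 || spec$p_adv_death > 1)
    stop("cancer-state outgoing probabilities exceed 1", call. = FALSE)
  if (any(life_table$qx < 0 | life_table$qx > 1))
    stop("life-table probabilities outside [0, 1]", call. = FALSE)

  occ <- setNames(c(1, 0, 0, 0, 0, 0), markov_states)
  delta <- spec$discount_rate
  trace <- list(occ)
  ly <- 0; qaly <- 0; cost <- 0
  k <- 0
  repeat {
    age <- spec$start_age + k
    q <- life_table_qx(life_table, age)
    alive <- occ[c("well", "benign_ooph", "early_oc", "advanced_oc")]
    w <- discount_weight(k, delta)

    p_e <- inc * spec$early_fraction
    p_a <- inc * (1 - spec$early_fraction)
    s <- 1 - q # survive other-cause mortality this cycle
    new <- setNames(numeric(6), markov_states)
    new["well"] <- occ[["well"]] * s * (1 - spec$p_benign - inc) +
      occ[["benign_ooph"]] * s
    new["benign_ooph"] <- occ[["well"]] * s * spec$p_benign
    new["early_oc"] <- occ[["well"]] * s * p_e +
      occ[["early_oc"]] * s * (1 - spec$p_early_death)
    new["advanced_oc"] <- occ[["well"]] * s * p_a +
      occ[["advanced_oc"]] * s * (1 - spec$p_adv_death)
    new["oc_death"] <- occ[["oc_death"]] +
      s * (occ[["early_oc"]] * spec$p_early_death +
             occ[["advanced_oc"]] * spec$p_adv_death)
    new["other_death"] <- occ[["other_death"]] + sum(alive) * q

    state_occ <- if (half_cycle) {
      (occ + new) / 2
    } else occ
    alive_occ <- state_occ[c("well", "benign_ooph", "early_oc",
                             "advanced_oc")]
    ly <- ly + w * sum(alive_occ)
    qaly <- qaly + w * sum(alive_occ * spec$utilities)
    screen_on <- spec$screening && age < spec$screening_stop_age
    cost <- cost + w * (if (screen_on)
      state_occ[["well"]] * spec$screen_cost else 0)
    # one-off entry costs, charged in the arrival cycle
    w1 <- discount_weight(k + 1, delta)
    cost <- cost +
      w1 * occ[["well"]] * s * (spec$p_benign * spec$benign_cost +
                                  p_e * spec$early_cost +
                                  p_a * spec$advanced_cost)

    occ <- new
    k <- k + 1
    trace[[k + 1]] <- occ
    if (sum(occ[c("well", "benign_ooph", "early_oc", "advanced_oc")]) <
        tol || age + 1 > max(life_table$age))
      break
  }
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  structure(list(trace = trace, life_years = unname(ly),
                 qalys = unname(qaly), cost = unname(cost), cycles = k,
                 spec = spec),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf(
    "Markov cohort (%s): %d cycles; LY %.4f, QALY %.4f, cost £%.2f (discount %.1f%%)\n",
    x$spec$strategy, x$cycles, x$life_years, x$qalys, x$cost,
    100 * x$spec$discount_rate))
  invisible(x)
}

#' Compare screening and no-screening Markov strategies
#'
#' @param spec_screen,spec_none [markov_spec()] objects sharing start age
#'   and discount rate.
#' @param life_table shared life table.
#' @param ... passed to [run_cohort()].
#' @return A list of class `cea_output`: per-strategy traces, `delta_ly`,
#'   `delta_qaly`, `delta_cost` and the `icer_result` (pounds per QALY).
#' @export
compare_strategies <- function(spec_screen, spec_none, life_table, ...) {
  stopifnot(inherits(spec_screen, "markov_spec"),
            inherits(spec_none, "markov_spec"))
  if (spec_screen$start_age != spec_none$start_age)
    stop("strategies have different start ages", call. = FALSE)
  if (abs(spec_screen$discount_rate - spec_none$discount_rate) > 1e-12)
    stop("strategies have different discount rates", call. = FALSE)
  a <- run_cohort(spec_screen, life_table, ...)
  b <- run_cohort(spec_none, life_table, ...)
  icer <- compute_icer(a$cost - b$cost, a$qalys - b$qalys)
  structure(list(screening = a, no_screening = b,
                 delta_ly = a$life_years - b$life_years,
                 delta_qaly = a$qalys - b$qalys,
                 delta_cost = a$cost - b$cost, icer = icer),
            class = "cea_output")
}

#' @export
print.cea_output <- function(x, ...) {
  cat(sprintf("dLY %.5f, dQALY %.5f, dCost £%.2f\n",
              x$delta_ly, x$delta_qaly, x$delta_cost))
  print(x$icer)
  invisible(x)
}

#' Probabilistic sensitivity analysis over the screening test cost
#'
#' Redraws the per-test CA125 cost from `Uniform(lo, hi)` each iteration,
#' rebuilds the screening strategy's well-state cost and reruns the
#' comparison. Everything else is held fixed, so the ICER is a monotone
#' function of the drawn cost and the sample extremes occur at the
#' boundary draws.
#'
#' @param spec_screen,spec_none strategy specifications.
#' @param life_table shared life table.
#' @param test_cost_range length-2 vector `c(lo, hi)` in pounds.
#' @param n_draws number of PSA iterations.
#' @param seed RNG seed (fixed seed gives identical output).
#' @return A list: `draws` (data frame of test cost and ICER per draw) and
#'   `summary` (min/median/mean/max ICER, base-case ICER).
#' @export
psa <- function(spec_screen, spec_none, life_table,
                test_cost_range = c(15, 50), n_draws = 100, seed = 1L) {
  if (length(test_cost_range) != 2 ||
      test_cost_range[1] > test_cost_range[2])
    stop("'test_cost_range' must be c(lo, hi) with lo <= hi",
         call. = FALSE)
  if (n_draws < 1) stop("'n_draws' must be >= 1", call. = FALSE)
  base <- compare_strategies(spec_screen, spec_none, life_table)
  set.seed(seed)
  tc <- runif(n_draws, test_cost_range[1], test_cost_range[2])
  icers <- vapply(tc, function(cost) {
    s <- spec_screen
    s$test_cost <- cost
    s$screen_cost <- cost + s$phlebotomy_cost + s$outpatient_cost
    compare_strategies(s, spec_none, life_table)$icer$ratio
  }, numeric(1))
  list(draws = data.frame(test_cost = tc, icer = icers),
       summary = c(min = min(icers), median = stats::median(icers),
                   mean = mean(icers), max = max(icers),
                   base = base$icer$ratio))
}
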