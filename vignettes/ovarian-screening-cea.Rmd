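---
title: "Methods: cost-effectiveness analysis of ovarian cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness analysis of ovarian cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ocscea` implements the economic-evaluation machinery for a large
three-arm randomised trial of annual ovarian cancer screening: a
no-screening control arm, a multimodal arm (serum CA125 interpreted by a
risk algorithm, with ultrasound as a second-line test; "MMS") and an
ultrasound-only arm ("USS"). The pipeline runs from patient-level records
(simulated or supplied as CSV) through within-trial incremental
cost-effectiveness ratios, a 25-year parametric extrapolation, and a
Markov cohort model with quality-adjusted life-years.

This vignette documents the models, the calibration of the synthetic
trial, and the numerical and design choices a maintainer would want
justified. It states no empirical results; the test suite and
`scripts/acceptance.R` compute those.

## The estimation problem

Ovarian cancer is rare but lethal: in a screening trial of roughly
200 000 women followed for about 14 years, only ~0.3% die of the disease,
and a mortality benefit emerges only after a lead time of about 7 years.
Within-trial incremental effects are therefore tiny (thousandths of a
discounted life-year), and the interesting economics happens in the tail:
the within-trial cost per life-year gained is an order of magnitude higher
than the value obtained once benefits are extrapolated over the cohort's
remaining lifetime. The package is organised so that each link in that
chain is a small, separately testable estimator.

## Discounting convention

Every estimator shares one convention: annual-step discounting with
weight $(1+\delta)^{-k}$ for follow-up year $k$ (0-indexed), so the first
year is undiscounted. The discounted restricted mean survival to horizon
$\tau$ is

$$\hat\mu(\tau,\delta) = \sum_{k\ge 0} (1+\delta)^{-k}
  \int_k^{\min(k+1,\tau)} \hat S(t)\,dt ,$$

with $\hat S$ the Kaplan–Meier curve. The convention was chosen because,
for a cohort with near-certain survival over ~13.56 years, it yields
discounted restricted means of ≈12.37 (at 1.5%) and ≈11.02 (at 3.5%) —
the magnitudes such trials report — whereas continuous-time discounting
gives visibly smaller values (≈12.27 at 1.5%). Costs, extrapolated
life-years and Markov cycles all reuse the same weights, so ratios are
internally consistent.

The restriction horizon defaults to the largest observed
event-or-censoring time (per arm table computations cap it so no arm's
curve is extrapolated); requesting a horizon beyond follow-up is an
error, never a silent extrapolation.

The variance of the discounted restricted mean generalises the standard
restricted-mean formula, replacing the plain residual area with the
discount-weighted one:
$\widehat{\mathrm{Var}} = \sum_{t_i\le\tau} A(t_i)^2\, d_i / \{n_i(n_i-d_i)\}$
with $A(t)=\int_t^\tau w(u)\hat S(u)\,du$.

## The synthetic trial generator

The generator (`generate_trial()`) is first-class, tested code: it defines
the study conditions under which the downstream estimators are validated.

**Structure.** Three arms with 2:1:1 allocation (101 299 / 50 624 /
50 623 women by default); entry staggered uniformly over 4.4 years;
administrative censoring at a common calendar end, so individual
follow-up is uniform on 9.2–13.6 years; annual screening from entry until
a calendar stop 10.6 years after recruitment began, giving 6–10 screens
per woman (median 8). Loss to follow-up is taken as negligible, so
censoring is purely administrative; the entry model is an approximation,
since trial reports rarely state the within-trial censoring distribution
precisely.

**Event model.** Time from randomisation to ovarian-cancer death is
piecewise exponential with a change-point at the 7-year lead time. Two
features are essential and jointly unobtainable from a constant baseline:
(i) the screened-arm hazard separates from control only after the lead
time, and (ii) the control arm's cumulative mortality keeps rising
steeply late in follow-up. The baseline hazard is therefore
$1.7001\times10^{-4}$ per woman-year before year 7 and 2.9964× that
afterwards, with post-lead-time hazard reductions of 23% (MMS) and 16.87%
(USS). These four constants were solved in closed form so that, in
expectation, the control arm's 14-year ovarian-cancer mortality is
0.343%, the MMS arm's overall mortality reduction is 15% (0.29%
death rate), the MMS reduction over years 7–14 is 23%, and the USS
overall reduction is 11%. A single constant baseline cannot satisfy
these simultaneously: with follow-up of 9.2–13.6 years only ~39% of
control deaths would fall after year 7, capping the overall reduction
near 9% when the late reduction is 23%.

**Cost histories.** Screened women accrue a per-screen cost each year
while alive, on-screen and undiagnosed (MMS: £20 test + £3 phlebotomy;
USS: £150 scan), plus a Bernoulli(0.02) second-line assessment scan per
screen. Women on a fatal disease trajectory are diagnosed
`diagnosis_lead` (default 2) years before their death time — diagnosis in
the death year itself would concentrate treatment costs in partial final
intervals where the censoring-adjusted estimator has no surviving
completers — and incur one stage-specific treatment cost (£3422 early /
£5666 advanced, the weighted surgery-plus-chemotherapy averages) in the
diagnosis year. Stage is Bernoulli: early with probability 0.45 under
screening and 0.25 without, reflecting the stage shift screening is meant
to produce. A diagnosis whose death falls beyond censoring still
contributes its treatment cost.

**What the generator does not emulate.** Non-fatal (cured) cancers,
screen-episode sensitivity/specificity, repeat-test protocols,
complication events and borderline histologies are out of scope; referral
behaviour enters only through the flat referral fraction. Consequently
absolute per-arm cost levels sit below those of a real trial arm (which
accrues treatment for non-fatal cancers and richer referral work-ups),
while between-arm cost *differences* — the quantity the ICERs consume —
have the right structure. Passing tests therefore validate the
estimators, and the arm-level mortality calibration, not absolute cost
levels.

**Seeding.** Each arm draws from its own stream derived from the master
seed, so resizing one arm never reshuffles another; event-time draws
precede cost draws, so changing unit costs never perturbs event
histories (this is what makes the univariate test-cost sweep an exact
ceteris-paribus experiment). Identical inputs give byte-identical output.

`true_rmst()` provides the closed-form discounted restricted mean under
the generating model, the oracle against which the Kaplan–Meier machinery
is checked for parameter recovery.

## Censoring-adjusted costs

Mean cost per patient uses the yearly-partition estimator: with
$\hat S(k)$ the Kaplan–Meier probability of being alive at the start of
year $k$ (deaths as events, censorings as censorings) and $\bar C_k$ the
mean year-$k$ cost,

$$\hat\mu_C = \sum_k (1+\delta)^{-k}\, \hat S(k)\, \bar C_k .$$

$\bar C_k$ averages over patients observed through the whole interval:
those under follow-up at $k+1$ plus those dying inside the interval
(their full interval cost is observed). Patients censored inside an
interval are excluded from that interval's cost mean — the
interval-complete rule — because their truncated cost observation would
bias $\bar C_k$ downward. Under no censoring the estimator reduces
exactly to the discounted sample-mean total cost.

The survival weight uses all-cause "alive and under observation"
survival; in the default generator other-cause mortality is zero, so this
coincides with the ovarian-cancer-death curve. Within the trial a single
pooled interval mean is used (the decedent/survivor split is an
extrapolation-period device, below). The variance comes from a
nonparametric bootstrap over patients (default 1000 replicates, seeded),
chosen over the analytic variance because the same bootstrap supplies the
cost–effect covariance the Fieller interval needs.

## ICERs and Fieller intervals

`compute_icer()` classifies each comparison on the cost-effectiveness
plane (trade-off, dominant, dominated, undefined at zero effect
difference) and never divides by a zero effect. Confidence limits for
$R=\Delta C/\Delta E$ come from Fieller's quadratic

$$(\Delta E^2 - z^2 v_E)R^2 - 2(\Delta C\,\Delta E - z^2 v_{CE})R
  + (\Delta C^2 - z^2 v_C) = 0 .$$

When the leading coefficient is not positive, the effect difference is
not significantly nonzero and the confidence set is unbounded; it is
reported as such, never truncated. With mortality differences as small as
these trials produce, the honest interval at trial scale is typically
unbounded — an important caveat when reading published point intervals.
Arms are independent, so $v_C$, $v_E$ and $v_{CE}$ are sums of within-arm
bootstrap moments; a zero-covariance analytic mode is available by
passing `covariance = 0`.

Monetary values are carried at full precision and rounded only at
rendering, which is why rendered ratios can differ slightly from division
of the rounded columns.

## Parametric extrapolation

Per arm, a flexible parametric model places a restricted cubic spline in
log time on the log cumulative hazard,
$\ln H(t) = \gamma_0 + \gamma_1 \ln t + \sum_j \gamma_j v_j(\ln t)$, with
interior knots at quantiles of the uncensored log event times and natural
(linear) tails — so long-range extrapolation is log-linear in cumulative
hazard, which tames the 25-year tail. `df = 1` is exactly Weibull.
Fitting maximises the right-censored log-likelihood by BFGS with analytic
gradients, initialised from a regression of the log Nelson–Aalen
cumulative hazard on log time; monotonicity of $H$ over the data range is
enforced by a quadratic penalty on a 101-point grid, and a fit that
remains non-monotone is rejected with an error rather than silently
accepted. Model complexity is chosen by AIC over `df ∈ {1, 2, 3}` (ties
toward the simpler model); the grid is a package default, kept small
because the event counts are modest.

Extrapolated life-years are hybrid by default: the nonparametric
discounted restricted mean within the trial, plus the spline's
conditional survival grafted at the trial end,
$\hat S_{KM}(\tau_0)\,S_m(t)/S_m(\tau_0)$, integrated year by year to the
horizon (default 25 years — the approximate life expectancy of a
60-year-old woman, the trial's median entry age). The hybrid keeps
published-style within-trial results untouched by parametric assumptions;
an all-parametric mode is behind the `hybrid` flag. No competing-risk
adjustment is applied in this module (the trial arms show no difference
in competing mortality; the Markov model handles competing death
instead) — extrapolated life-years are therefore deliberately generous to
both arms equally.

Extrapolated costs use the two-component method: for each post-trial year,
expected survivors accrue the survivor annual cost and expected decedents
the decedent annual cost, both estimated from within-trial observed
annual costs (`annual_cost_components()`) and weighted by the parametric
survival. Costs are assumed to continue on their within-trial pattern —
screening, testing and treatment — to the end of the extrapolation
period; a screening-stop age is not imposed by default but is available
in the Markov module. The sum runs over whole years from
`ceiling(trial_end)`; the sub-year sliver between the trial end and the
next year boundary is dropped (its weight is a fraction of one year at
survival ≈ 1 in both arms, so it cancels from differences to first
order).

## Markov cohort model

A deterministic annual-cycle cohort starts at age 60 in `well` and moves
through `benign_ooph` (a one-cycle tunnel: oophorectomy is a one-off
surgical event with a one-off £2275 + £139 cost, returning to `well`),
`early_oc` and `advanced_oc` (persistent until death, charged their
weighted treatment cost once on entry), `oc_death` and `other_death`.
Life-table mortality applies first each cycle in every alive state, and
disease transitions act on the survivors, so each row of the transition
matrix sums to one by construction and remains valid at the table's
terminal `qx = 1`. Validation of the probability budgets happens before
any cycling.

Accrual is state-at-cycle-start with cycle 0 undiscounted, matching the
pipeline-wide discounting convention; a half-cycle correction is behind a
flag and off by default so that the discrete annuity identities used for
verification hold exactly. Utilities are 0.718 (early) and 0.649
(advanced) — stable vs progressive disease tariffs from the ovarian
cancer quality-of-life literature — and 1.0 for `well` and
`benign_ooph`, which the tariff sources leave unstated. Under screening,
every well-year is charged £20 (test) + £3 (phlebotomy) + £109
(specialist outpatient visit); the outpatient component is charged per
well-year on a literal reading of the costing description, and a
per-referral alternative can be expressed by scaling the outpatient cost.

**Transition inputs.** The source analysis derived its transition
probabilities from within-trial annual hazards it did not publish. The
package's defaults are therefore its own calibration to the trial's
qualitative structure, at realistic epidemiological magnitudes: annual
cancer incidence $6\times10^{-4}$; early-stage fraction 0.45 under
screening vs 0.25 without (the stage shift is the mechanism of benefit);
benign-surgery probability $1.4\times10^{-3}$ vs $3\times10^{-4}$
(screening generates false-positive surgery); annual ovarian-cancer death
probability 0.02 from the early state and 0.30 from the advanced state
(early-stage disease is mostly survivable, advanced disease mostly not).
All are overridable, and absolute Markov ICER levels should be read as
illustrative: the structural properties (trade-off quadrant, monotonicity
in costs and in the stage shift, conservation, life-table consistency)
are the tested surface.

The life table is a Gompertz stand-in, $\mu(x) = A e^{B(x-60)}$ with
$A = 4.93693\times10^{-3}$ and $B = 0.105$, calibrated so the complete
life expectancy at 60 is 25.22 years; it ships as
`inst/extdata/synthetic_uk_female_life_table.csv` and is labelled
synthetic — substitute a national table via `read_life_table()` for real
analyses.

The probabilistic sensitivity analysis redraws the per-test cost from
Uniform(£15, £50) — the sensitivity range quoted for the test's unknown
public-sector price; a £10–£50 variant appears in some result summaries
and can be requested explicitly. Because nothing else varies, the ICER is
monotone in the drawn cost and the PSA extremes sit at the boundary
draws; this is by design and is asserted in the tests.

## Numerical choices and degenerate inputs

* Step-curve integrals split segments at integer years so each piece has
  one discount weight; quadrature over parametric survival uses adaptive
  integration at `rel.tol = 1e-10` per year segment.
* Kaplan–Meier ties: deaths before censorings (the `survival` package
  convention); a censoring exactly at a year boundary completes that
  year's cost interval.
* Empty cost intervals (weight positive but no complete observer)
  contribute zero — they arise only in the final partial year.
* Spline fits reject all-censored arms, fewer events than parameters,
  and degenerate (concentrated) knot placements with informative errors.
* Cohort cycling stops below an alive mass of $10^{-9}$ or at the end of
  the life table, whose final age carries `qx = 1`.
* The Fieller discriminant can fall below zero only at the boundary of
  significance; that case is reported as unbounded.

## Problem sizes

The test suite validates estimator mathematics on small constructed
fixtures (5–200 records) where oracles can be enumerated by hand,
property-style behaviour on moderate simulated trials (600–5000 women
with amplified event rates so that effect signs are stable), and
calibration on full-scale trials (202 546 women). The acceptance script
averages replicate full-scale trials (default 256) because a single
replicate holds only ~350 control-arm deaths and rate ratios built on
such counts carry several percentage points of binomial noise; averaging
is variance reduction of the reported estimate and leaves the study
conditions untouched.

## Known limitations

* Absolute cost levels in the generator omit non-fatal-cancer treatment;
  only cost differences are structurally faithful.
* The Fieller intervals reproduce honest trial-scale uncertainty, which
  is typically an unbounded set; published narrow intervals for such
  ratios cannot be reconstructed without the unpublished variance inputs.
* The Markov transition defaults are calibrated, not estimated from real
  data; absolute £/QALY outputs are illustrative.
* The extrapolation assumes the fitted hazard separation persists to the
  horizon; if real-world screening effects attenuate after screening
  stops, extrapolated gains are optimistic.
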