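Package: ocscea
Title: Cost-Effectiveness Analysis of Ovarian Cancer Screening Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-trial and extrapolated cost-effectiveness analysis of
    annual ovarian cancer screening programmes against no screening, built
    around patient-level randomised-trial data. Provides a calibrated
    synthetic trial generator (three arms, staggered entry, delayed
    screening effect on a piecewise-exponential ovarian-cancer mortality
    hazard, yearly cost accrual), discounted restricted mean survival from
    Kaplan-Meier curves, censoring-adjusted mean costs via the yearly
    partition estimator with survival weights, incremental
    cost-effectiveness ratios with Fieller confidence intervals and
    univariate test-cost sweeps, Royston-Parmar flexible parametric
    survival models with AIC selection for 25-year extrapolation of
    life-years and two-component costs, and an annual-cycle Markov cohort
    model with life-table competing mortality, QALYs and probabilistic
    sensitivity analysis over the screening test cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    withr
Config/testthat/edition: 3
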