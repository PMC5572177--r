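# Configuration, orchestration and table rendering for full pipeline runs.

#' Pipeline configuration
#'
#' Bundles every stage's parameters with the defaults used throughout the
#' package: the trial generator at full emulated scale, discount rates
#' {0, 1.5%, 3.5%}, a 25-year extrapolation with spline complexities 1-3,
#' and the Markov comparison with a uniform £15-£50 PSA over the test cost.
#'
#' @param design,hazard,costs trial generator parameters.
#' @param discount_rates vector of annual discount rates for the
#'   within-trial tables.
#' @param alpha Fieller significance level.
#' @param n_bootstrap bootstrap replicates for variances/covariances.
#' @param seed master seed; stage sub-seeds (generator, bootstrap, PSA) are
#'   derived from it so stages are independently reproducible.
#' @param horizon extrapolation horizon (years).
#' @param df_grid spline complexities for AIC selection.
#' @param test_costs univariate sweep grid (pounds per test).
#' @param markov_screen,markov_none Markov strategy specifications.
#' @param life_table life table for the Markov model.
#' @param psa_range,psa_draws PSA settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = trial_design(),
                            hazard = hazard_spec(),
                            costs = cost_model(),
                            discount_rates = c(0, 0.015, 0.035),
                            alpha = 0.05, n_bootstrap = 200, seed = 1L,
                            horizon = 25, df_grid = 1:3,
                            test_costs = c(15, 30, 40, 50),
                            markov_screen = markov_spec("screening"),
                            markov_none = markov_spec("no_screening"),
                            life_table = gompertz_life_table(),
                            psa_range = c(15, 50), psa_draws = 100) {
  if (any(discount_rates < 0))
    stop("discount rates must be non-negative", call. = FALSE)
  if (horizon <= design$max_followup)
    stop("'horizon' must exceed the trial follow-up", call. = FALSE)
  structure(list(design = design, hazard = hazard, costs = costs,
                 discount_rates = discount_rates, alpha = alpha,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed),
                 horizon = horizon, df_grid = df_grid,
                 test_costs = test_costs, markov_screen = markov_screen,
                 markov_none = markov_none, life_table = life_table,
                 psa_range = psa_range, psa_draws = psa_draws),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads scalar overrides from a YAML file with (optional) sections
#' `trial` (keys of [trial_design()], [hazard_spec()], [cost_model()]),
#' `analysis`, `extrapolation` and `markov`, merged over the package
#' defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(section, fn) {
    args <- y[[section]]
    args <- args[names(args) %in% names(formals(fn))]
    args
  }
  design <- do.call(trial_design, take("trial", trial_design))
  hazard <- do.call(hazard_spec, take("trial", hazard_spec))
  costs <- do.call(cost_model, take("trial", cost_model))
  an <- y[["analysis"]]
  ex <- y[["extrapolation"]]
  mk <- y[["markov"]]
  args <- list(design = design, hazard = hazard, costs = costs)
  for (nm in c("discount_rates", "alpha", "n_bootstrap", "seed"))
    if (!is.null(an[[nm]])) args[[nm]] <- an[[nm]]
  for (nm in c("horizon", "df_grid", "test_costs"))
    if (!is.null(ex[[nm]])) args[[nm]] <- ex[[nm]]
  if (!is.null(mk)) {
    mk_args <- mk[names(mk) %in% names(formals(markov_spec))]
    args$markov_screen <- do.call(markov_spec,
                                  c(list(strategy = "screening"), mk_args))
    args$markov_none <- do.call(markov_spec,
                                c(list(strategy = "no_screening"), mk_args))
    if (!is.null(mk$life_table_path))
      args$life_table <- read_life_table(mk$life_table_path)
    if (!is.null(mk$psa_range)) args$psa_range <- mk$psa_range
    if (!is.null(mk$psa_draws)) args$psa_draws <- mk$psa_draws
  }
  do.call(pipeline_config, args)
}

config_digest <- function(config) {
  flat <- utils::capture.output(utils::str(
    config[setdiff(names(config), "life_table")], give.attr = FALSE))
  text_digest(flat)
}

#' Run the full cost-effectiveness pipeline
#'
#' Simulate, estimate within-trial effects (restricted-mean table) and
#' costs (censoring-adjusted table), form within-trial ICERs with Fieller
#' intervals, sweep the test cost, extrapolate to the configured horizon,
#' and run the Markov comparison with PSA. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("within_trial", "sweep", "extrapolation", "markov")` to run after
#'   simulation.
#' @return A list of class `cea_report` holding each stage's table plus
#'   the configuration digest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("within_trial", "sweep",
                                    "extrapolation", "markov")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  digest <- config_digest(config)
  seed_gen <- config$seed
  seed_boot <- config$seed + 1000L
  seed_psa <- config$seed + 2000L
  message(sprintf("[ocscea %s] simulate: seed %d", digest, seed_gen))
  records <- generate_trial(config$design, config$hazard, config$costs,
                            seed_gen)
  bundle <- list(config_digest = digest, seed = config$seed)

  if ("within_trial" %in% stages) {
    message(sprintf("[ocscea %s] within-trial tables", digest))
    bundle$effects <- rmst_table(records, config$discount_rates)
    bundle$costs <- cost_table(records, config$discount_rates,
                               n_bootstrap = config$n_bootstrap,
                               seed = seed_boot)
    icers <- list()
    for (a in c("mms", "uss")) {
      for (d in setdiff(config$discount_rates, 0)) {
        r <- icer_within_trial(records, arm = a, ref = "control",
                               discount_rate = d, alpha = config$alpha,
                               n_bootstrap = config$n_bootstrap,
                               seed = seed_boot)
        icers[[length(icers) + 1L]] <- data.frame(
          comparison = paste0(a, " vs control"), discount_rate = d,
          delta_cost = r$delta_cost, delta_effect = r$delta_effect,
          icer = r$ratio, classification = r$classification,
          ci_low = r$ci_low, ci_high = r$ci_high)
      }
    }
    bundle$icers <- do.call(rbind, icers)
  }
  if ("sweep" %in% stages) {
    message(sprintf("[ocscea %s] test-cost sweep", digest))
    bundle$sweep <- univariate_sweep(
      config$design, config$hazard, config$costs, config$test_costs,
      discount_rate = 0.015, seed = seed_gen)
  }
  if ("extrapolation" %in% stages) {
    message(sprintf("[ocscea %s] extrapolation to %d y", digest,
                    config$horizon))
    rows <- lapply(setdiff(config$discount_rates, 0), function(d) {
      e <- extrapolate_icer(records, horizon = config$horizon,
                            discount_rate = d, df_grid = config$df_grid)
      data.frame(discount_rate = d, delta_cost = e$delta_cost,
                 delta_lyg = e$delta_lyg, icer = e$icer,
                 df_a = e$model_a$df, df_b = e$model_b$df)
    })
    bundle$extrapolation <- do.call(rbind, rows)
  }
  if ("markov" %in% stages) {
    message(sprintf("[ocscea %s] Markov cohort + PSA", digest))
    cmp <- compare_strategies(config$markov_screen, config$markov_none,
                              config$life_table)
    bundle$markov <- data.frame(
      delta_ly = cmp$delta_ly, delta_qaly = cmp$delta_qaly,
      delta_cost = cmp$delta_cost, icer = cmp$icer$ratio,
      classification = cmp$icer$classification)
    p <- psa(config$markov_screen, config$markov_none, config$life_table,
             test_cost_range = config$psa_range,
             n_draws = config$psa_draws, seed = seed_psa)
    bundle$psa <- as.data.frame(t(p$summary))
    bundle$psa_draws <- p$draws
  }
  class(bundle) <- "cea_report"
  bundle
}

#' Render pipeline tables
#'
#' Formats the report bundle's tables for presentation: currency to the
#' nearest pound, effects to 5 decimal places (all values are carried at
#' full precision internally and rounded only here). Ratios can differ
#' from straight division of the rounded columns because of that rounding.
#'
#' @param bundle a `cea_report` from [run_pipeline()].
#' @return Named list of formatted data frames (one per available table);
#'   missing stages are skipped with a warning.
#' @export
render_tables <- function(bundle) {
  stopifnot(inherits(bundle, "cea_report"))
  out <- list()
  money <- function(x) round(x)
  eff <- function(x) round(x, 5)
  if (!is.null(bundle$effects)) {
    tab <- bundle$effects
    tab$mean <- eff(tab$mean)
    tab$se <- signif(tab$se, 3)
    out$effects <- tab
  }
  if (!is.null(bundle$costs)) {
    tab <- bundle$costs
    tab$mean <- money(tab$mean)
    out$costs <- tab
  }
  if (!is.null(bundle$icers)) {
    tab <- bundle$icers
    for (col in c("delta_cost", "icer", "ci_low", "ci_high"))
      tab[[col]] <- money(tab[[col]])
    tab$delta_effect <- eff(tab$delta_effect)
    out$icers <- tab
  }
  if (!is.null(bundle$sweep)) {
    tab <- bundle$sweep
    tab$delta_cost <- money(tab$delta_cost)
    tab$icer <- money(tab$icer)
    tab$delta_effect <- eff(tab$delta_effect)
    out$sweep <- tab
  } else {
    warning("sensitivity sweep missing from bundle; table omitted",
            call. = FALSE)
  }
  if (!is.null(bundle$extrapolation)) {
    tab <- bundle$extrapolation
    tab$delta_cost <- money(tab$delta_cost)
    tab$icer <- money(tab$icer)
    tab$delta_lyg <- eff(tab$delta_lyg)
    out$extrapolation <- tab
  }
  if (!is.null(bundle$markov)) {
    tab <- bundle$markov
    tab$delta_cost <- money(tab$delta_cost)
    tab$icer <- money(tab$icer)
    out$markov <- tab
  }
  out
}

#' Write a pipeline report to disk
#'
#' One CSV per table (each with a header comment carrying the
#' configuration digest) plus a JSON summary of the whole bundle.
#'
#' @param bundle a `cea_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cea_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- render_tables(bundle)
  for (nm in names(tabs)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    writeLines(sprintf("# ocscea config %s seed %d", bundle$config_digest,
                       bundle$seed), path)
    suppressWarnings(utils::write.table(
      tabs[[nm]], path, sep = ",", row.names = FALSE, append = TRUE))
  }
  json <- report_json(bundle)
  writeLines(json, file.path(dir, "summary.json"))
  invisible(dir)
}

report_json <- function(bundle) {
  payload <- bundle[setdiff(names(bundle), "psa_draws")]
  class(payload) <- NULL
  jsonlite::toJSON(payload, dataframe = "rows", digits = NA,
                   auto_unbox = TRUE, pretty = TRUE, na = "null")
}
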