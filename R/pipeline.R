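#' Default run configuration
#'
#' The pipeline is driven by a flat configuration list (serialisable as
#' YAML): data source (packaged synthetic inputs, optionally with Poisson
#' count noise, or CSV paths), trend-fit options, model options, the
#' scenario list, and the Monte Carlo block. Every stochastic element
#' draws from substreams derived from the single top-level `seed`, so a
#' run is fully reproducible from its config.
#'
#' @return A nested list with the documented defaults.
#' @export
default_run_config <- function() {
  list(
    seed = NULL,                    # NULL = deterministic synthetic inputs
    data = list(
      source = "synthetic",         # or "csv"
      series_csv = NULL,            # mortality series (sex, age_band, year,
                                    #   population, deaths)
      population_csv = NULL         # population incl. projection year
    ),
    trend = list(method = "ols_log", continuity_correction = FALSE),
    model = list(form = "linear", frac_pufa = 0.90, frac_mufa = 0.10,
                 hyp_prev = 0.37),
    scenarios = c("trend_only", "low_sfa_10E", "high_sfa_20E"),
    mc = list(enabled = FALSE, n_draws = 10000),
    out_dir = NULL
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown scenarios, invalid option values and inconsistent data blocks
#' are collected and reported together in one validation error.
#'
#' @param path Path to a YAML file; keys override [default_run_config()].
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  problems <- character()
  if (!cfg$data$source %in% c("synthetic", "csv")) {
    problems <- c(problems, paste0("data$source must be 'synthetic' or 'csv', got '",
                                   cfg$data$source, "'"))
  }
  if (cfg$data$source == "csv" &&
      (is.null(cfg$data$series_csv) || is.null(cfg$data$population_csv))) {
    problems <- c(problems,
                  "data$source = 'csv' requires series_csv and population_csv")
  }
  if (cfg$data$source == "synthetic" &&
      (!is.null(cfg$data$series_csv) || !is.null(cfg$data$population_csv))) {
    problems <- c(problems,
                  "data$source = 'synthetic' must not also set CSV paths")
  }
  if (!cfg$trend$method %in% c("ols_log", "poisson")) {
    problems <- c(problems, paste0("trend$method must be 'ols_log' or 'poisson', got '",
                                   cfg$trend$method, "'"))
  }
  if (!cfg$model$form %in% c("linear", "loglinear")) {
    problems <- c(problems, paste0("model$form must be 'linear' or 'loglinear', got '",
                                   cfg$model$form, "'"))
  }
  if (abs(cfg$model$frac_pufa + cfg$model$frac_mufa - 1) > 1e-9) {
    problems <- c(problems, "model$frac_pufa + model$frac_mufa must equal 1")
  }
  if (cfg$model$hyp_prev < 0 || cfg$model$hyp_prev > 1) {
    problems <- c(problems, "model$hyp_prev must be in [0, 1]")
  }
  known <- c("trend_only", "low_sfa_10E", "high_sfa_20E", "null")
  bad <- setdiff(cfg$scenarios, known)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("unknown scenario(s): ",
                                   paste(bad, collapse = ", "),
                                   " (available: ",
                                   paste(known, collapse = ", "), ")"))
  }
  if (isTRUE(cfg$mc$enabled) && is.null(cfg$seed)) {
    problems <- c(problems, "a top-level seed is mandatory when mc$enabled")
  }
  if (length(problems) > 0) {
    stop("Invalid run configuration:\n",
         paste0("  - ", problems, collapse = "\n"), call. = FALSE)
  }
  cfg
}

scenario_by_name <- function(name) {
  switch(name,
    trend_only = scenario_trend_only(),
    low_sfa_10E = scenario_low_sfa(),
    high_sfa_20E = scenario_high_sfa(),
    null = scenario_null(),
    stop("Unknown scenario: ", name, call. = FALSE)
  )
}

#' Run the full projection pipeline
#'
#' Orchestrates the end-to-end analysis: assemble inputs, fit per-stratum
#' exponential decay trends, project baseline expected deaths to 2025 and
#' the constant-rate counterfactual, evaluate each configured scenario
#' through the DPP engine, and (optionally) attach Monte Carlo uncertainty
#' intervals. When `out_dir` is set, the projection and DPP tables are
#' written as CSV and a markdown summary as `summary.md`.
#'
#' @param config A config list (see [default_run_config()],
#'   [read_run_config()]).
#' @return A list of class `chd_pipeline_result`: `inputs`, `fits`,
#'   `baseline_2025` / `counterfactual_2025` ([expected_deaths()]
#'   objects), `percent_decline`, `scenarios` (named list of
#'   [run_scenario()] results), `mc` (named list of
#'   `uncertainty_intervals` or `NULL`), `config`, and `log` (parameters
#'   actually used).
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(config)
  seed <- config$seed

  if (config$data$source == "synthetic") {
    inputs <- synthetic_sweden(seed = seed)
  } else {
    series <- read_mortality_csv(config$data$series_csv)
    pop <- read_population_csv(config$data$population_csv)
    inputs <- structure(list(
      series = series,
      deaths_2010 = series[series$year == 2010,
                           c("sex", "age_band", "population", "deaths")],
      population_2025 = pop[pop$year == 2025, ],
      risk_factors_2010 = swedish_risk_factors(2010)$by_stratum,
      diet = diet_profile(),
      params = default_effect_parameters()
    ), class = "chd_inputs")
  }
  # model options override the packaged constants
  cst <- inputs$params$constants
  cst$hyp_prev <- config$model$hyp_prev
  inputs$params$constants <- cst
  mix <- replacement_mix(config$model$frac_pufa, config$model$frac_mufa)

  fits <- fit_all_strata(inputs$series, method = config$trend$method,
                         continuity_correction = config$trend$continuity_correction)
  baseline <- expected_deaths(fits, 2025, inputs$population_2025)
  counterfactual <- expected_deaths(fits, 2025, inputs$population_2025,
                                    constant_rate = TRUE)
  pct_decline <- 100 * (counterfactual$total - baseline$total) /
    counterfactual$total

  scenarios <- list()
  mc <- list()
  for (nm in config$scenarios) {
    sc <- scenario_by_name(nm)
    sc$mix <- mix
    scenarios[[nm]] <- run_scenario(sc, inputs, fits = fits,
                                    form = config$model$form)
    if (isTRUE(config$mc$enabled)) {
      mc[[nm]] <- mc_scenario(sc, inputs, fits = fits,
                              n_draws = config$mc$n_draws,
                              seed = seed + 2000L,
                              form = config$model$form)
    }
  }

  result <- structure(
    list(
      inputs = inputs, fits = fits,
      baseline_2025 = baseline, counterfactual_2025 = counterfactual,
      percent_decline = pct_decline,
      scenarios = scenarios,
      mc = if (length(mc) > 0) mc else NULL,
      config = config,
      log = list(
        seed = seed, trend_method = config$trend$method,
        form = config$model$form,
        frac_pufa = config$model$frac_pufa,
        frac_mufa = config$model$frac_mufa,
        hyp_prev = config$model$hyp_prev,
        constants = inputs$params$constants,
        mc_n_draws = if (isTRUE(config$mc$enabled)) config$mc$n_draws else NA
      )
    ),
    class = "chd_pipeline_result"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_projection_csv(result, file.path(config$out_dir, "projection.csv"))
    write_dpp_csv(result, file.path(config$out_dir, "dpp.csv"))
    writeLines(render_summary(result), file.path(config$out_dir, "summary.md"))
  }
  result
}

#' Render a markdown summary of a pipeline run
#'
#' Reports the baseline projection, the constant-rate counterfactual, the
#' percent decline, and a per-factor-by-sex DPP table for every scenario
#' (raw-value accounting, rounded to the nearest 5 for display, with the
#' percentage of baseline expected deaths to one decimal).
#'
#' @param result A `chd_pipeline_result`.
#' @return Character vector of markdown lines.
#' @export
render_summary <- function(result) {
  stopifnot(inherits(result, "chd_pipeline_result"))
  b <- result$baseline_2025
  cf <- result$counterfactual_2025
  lines <- c(
    "# CHD mortality projection summary",
    "",
    sprintf("- Baseline expected CHD deaths in 2025 (continued decline): **%d** (%s)",
            as.integer(round_to_5(b$total)),
            paste(sprintf("%s %d", b$by_sex$sex,
                          as.integer(round_to_5(b$by_sex$expected_deaths))),
                  collapse = ", ")),
    sprintf("- Constant-rate counterfactual (2010 rates held): **%d**",
            as.integer(round_to_5(cf$total))),
    sprintf("- Percent decline vs counterfactual: **%.0f%%**",
            result$percent_decline),
    ""
  )
  for (nm in names(result$scenarios)) {
    res <- result$scenarios[[nm]]
    lines <- c(lines, sprintf("## Scenario: %s (%s form)", nm, res$form), "",
               "| factor | male | female | total |",
               "|---|---|---|---|")
    for (f in unique(res$by_factor$factor)) {
      sub <- res$by_factor[res$by_factor$factor == f, ]
      m <- sub$dpp_raw[sub$sex == "male"]
      w <- sub$dpp_raw[sub$sex == "female"]
      lines <- c(lines, sprintf("| %s | %d | %d | %d |", f,
                                as.integer(round_to_5(m)),
                                as.integer(round_to_5(w)),
                                as.integer(round_to_5(m + w))))
    }
    lines <- c(lines, sprintf(
      "| **total DPP** | %d | %d | %d |",
      as.integer(round_to_5(res$by_sex$dpp_raw[res$by_sex$sex == "male"])),
      as.integer(round_to_5(res$by_sex$dpp_raw[res$by_sex$sex == "female"])),
      as.integer(round_to_5(res$total_dpp))), "",
      sprintf("Total DPP is %.1f%% of baseline expected deaths; net expected deaths in 2025: %d.",
              100 * res$total_dpp / res$baseline_2025,
              as.integer(round_to_5(res$net_2025))), "")
    if (!is.null(result$mc[[nm]])) {
      ui <- result$mc[[nm]]
      tot <- ui[ui$quantity == "total_dpp", ]
      lines <- c(lines, sprintf(
        "95%% uncertainty interval for total DPP: %d to %d (%d draws).",
        as.integer(round_to_5(tot$low)), as.integer(round_to_5(tot$high)),
        tot$n_draws), "")
    }
  }
  lines
}

#' @export
print.chd_pipeline_result <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

# ---- CSV schemas ---------------------------------------------------------

#' Read and write the pipeline CSV schemas
#'
#' Long-format CSV schemas used by the analysis scripts: mortality series
#' (`sex, age_band, year, population, deaths, rate`), population
#' (`sex, age_band, year, population`), per-stratum projection
#' (`sex, age_band, year, rate, expected_deaths`) and tidy DPP results
#' (`scenario, sex, age_band, factor, dpp_raw, dpp_rounded`). Values
#' round-trip exactly (doubles are written with shortest round-trippable
#' representation).
#'
#' @param df,result Object to write.
#' @param path File path.
#' @return The written tibble (write) or the parsed tibble (read).
#' @name chd_csv
NULL

#' @rdname chd_csv
#' @export
write_mortality_csv <- function(df, path) {
  # `rate` is derived (deaths/population) and is recomputed on read, so the
  # round trip is exact even where a decimal rendering of the rate is not
  df <- df[, setdiff(names(df), "rate")]
  readr::write_csv(df, path)
  invisible(df)
}

#' @rdname chd_csv
#' @export
read_mortality_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sex", "age_band", "year", "population", "deaths")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("Mortality CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"rate" %in% names(df)) df$rate <- df$deaths / df$population
  normalise_strata(df)
}

#' @rdname chd_csv
#' @export
read_population_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sex", "age_band", "year", "population")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("Population CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  normalise_strata(df)
}

#' @rdname chd_csv
#' @export
write_projection_csv <- function(result, path) {
  out <- dplyr::bind_rows(
    dplyr::mutate(result$baseline_2025$by_stratum, projection = "trend"),
    dplyr::mutate(result$counterfactual_2025$by_stratum,
                  projection = "constant_rate")
  )
  readr::write_csv(out, path)
  invisible(out)
}

#' @rdname chd_csv
#' @export
write_dpp_csv <- function(result, path) {
  out <- dplyr::bind_rows(lapply(result$scenarios, function(r) r$results))
  if (!is.null(result$mc)) {
    ui <- dplyr::bind_rows(lapply(names(result$mc), function(nm) {
      x <- result$mc[[nm]]
      x$scenario <- nm
      x
    }))
    attr(out, "uncertainty") <- ui
  }
  readr::write_csv(out, path)
  invisible(out)
}

#' @rdname chd_csv
#' @export
read_dpp_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
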