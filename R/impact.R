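#' Population attributable risk fraction
#'
#' `PARF = p * (rr - 1) / (1 + p * (rr - 1))`: the share of mortality that
#' would be removed by eliminating a binary exposure with prevalence `p`
#' and relative risk `rr`. Vectorised; for `rr >= 1` the value lies in
#' \[0, 1). Protective exposures (`rr < 1`) yield negative values, with a
#' warning.
#'
#' @param p Exposure prevalence(s) in \[0, 1\].
#' @param rr Relative risk(s), > 0.
#' @return PARF value(s).
#' @examples
#' parf(0.5, 3)   # 0.5
#' @export
parf <- function(p, rr) {
  if (any(p < 0 | p > 1)) stop("prevalence must be in [0, 1]", call. = FALSE)
  if (any(rr <= 0)) stop("relative risk must be positive", call. = FALSE)
  if (any(rr < 1)) {
    warning("rr < 1 (protective exposure): PARF is negative", call. = FALSE)
  }
  excess <- p * (rr - 1)
  excess / (1 + excess)
}

#' Deaths prevented or postponed from a continuous risk-factor change
#'
#' The regression route for continuous factors (total cholesterol, SBP):
#' baseline deaths times the absolute risk-factor change times a
#' stratum-specific coefficient giving the relative mortality change per
#' unit. Signs follow the convention that an improvement (negative
#' `delta_rf` for a harmful factor) yields a positive number of deaths
#' prevented or postponed.
#'
#' The `"linear"` form is the literal product
#' `deaths * |delta| * beta`; the `"loglinear"` form,
#' `deaths * (1 - exp(-beta * |delta|))`, is the classic IMPACT variant
#' that cannot exceed the baseline deaths. They agree to first order in
#' `beta * |delta|`.
#'
#' @param deaths Baseline CHD deaths in the stratum (>= 0).
#' @param delta_rf Signed risk-factor change (e.g. mmol/L or mm Hg).
#' @param beta Relative mortality change per unit of the factor (> 0 for a
#'   harmful factor).
#' @param form `"linear"` (default) or `"loglinear"`.
#' @return Signed deaths prevented or postponed (vectorised).
#' @examples
#' dpp_regression(1000, -0.5, 0.30)                      # 150
#' dpp_regression(1000, -0.5, 0.30, form = "loglinear")  # ~139.3
#' @export
dpp_regression <- function(deaths, delta_rf, beta,
                           form = c("linear", "loglinear")) {
  form <- match.arg(form)
  if (any(deaths < 0)) stop("deaths must be >= 0", call. = FALSE)
  magnitude <- switch(form,
    linear = deaths * abs(delta_rf) * beta,
    loglinear = deaths * (1 - exp(-beta * abs(delta_rf)))
  )
  # improvement (delta < 0) => deaths prevented (positive)
  magnitude * -sign(delta_rf)
}

#' Deaths prevented or postponed from a change in PARF
#'
#' The attributable-fraction route for binary factors (smoking, physical
#' inactivity): projected deaths in the target year multiplied by the
#' difference between the baseline-year and target-year PARF. A fall in
#' prevalence lowers the PARF and yields a positive number of deaths
#' prevented.
#'
#' @param expected_deaths Expected deaths in the projection year.
#' @param parf_before,parf_after PARF at baseline and under the scenario,
#'   each in (-1, 1).
#' @return Signed deaths prevented or postponed (vectorised).
#' @examples
#' dpp_parf(1000, 0.25, 0.15)   # 100
#' @export
dpp_parf <- function(expected_deaths, parf_before, parf_after) {
  if (any(abs(parf_before) >= 1) || any(abs(parf_after) >= 1)) {
    stop("PARF values must lie in (-1, 1)", call. = FALSE)
  }
  expected_deaths * (parf_before - parf_after)
}

#' Round death counts to the nearest 5
#'
#' Reported DPP values are conventionally rounded to the nearest multiple
#' of 5; ties round away from zero. Rounding is applied at reporting time
#' only — all internal accounting uses raw values, so totals are sums of
#' unrounded parts.
#'
#' @param x Signed death count(s).
#' @return Integer multiple(s) of 5.
#' @examples
#' round_to_5(c(378, 812.4, 2.5, -2.5))
#' @export
round_to_5 <- function(x) {
  sign(x) * 5 * floor(abs(x) / 5 + 0.5)
}

#' Define a risk-factor scenario
#'
#' A scenario specifies target changes between the baseline year (2010)
#' and the projection year (2025): an optional target saturated-fat intake
#' (with sex-specific baseline intakes), a salt intake change, and
#' absolute prevalence changes for smoking and physical inactivity applied
#' uniformly to every age band.
#'
#' Three presets mirror the published analysis:
#' \describe{
#'   \item{`scenario_low_sfa()`}{saturated fat falls to 10 E% (Nordic
#'     Nutrition Recommendations level) from sex-specific baselines of
#'     15.9 E% (men) / 14.4 E% (women), plus the assumed favourable
#'     trends: salt -1 g/day, smoking -5 percentage points, inactivity
#'     -5 percentage points.}
#'   \item{`scenario_high_sfa()`}{saturated fat rises to 20 E% (recent
#'     high-fat dietary trend) from baselines 17.5 / 16.0 E%, same
#'     favourable trends in the other factors.}
#'   \item{`scenario_trend_only()`}{no dietary fat change; only the
#'     favourable salt / smoking / inactivity trends.}
#' }
#'
#' @param name Scenario label.
#' @param target_sfa Target saturated-fat intake, E%, or `NULL` for no
#'   dietary fat change.
#' @param baseline_sfa Named numeric (names `"male"`, `"female"`):
#'   sex-specific baseline saturated-fat intakes, E%.
#' @param salt_delta Signed change in salt intake, g/day.
#' @param smoking_delta,inactivity_delta Signed absolute prevalence
#'   changes (fractions; -0.05 means a 5-percentage-point reduction).
#'   Reductions are floored at zero prevalence per stratum; increases that
#'   push any stratum's prevalence above 1 are an error.
#' @param mix Fat [replacement_mix()].
#' @return A list of class `chd_scenario`.
#' @export
chd_scenario <- function(name, target_sfa = NULL,
                         baseline_sfa = c(male = 15.9, female = 14.4),
                         salt_delta = 0, smoking_delta = 0,
                         inactivity_delta = 0, mix = replacement_mix()) {
  structure(
    list(name = name, target_sfa = target_sfa, baseline_sfa = baseline_sfa,
         salt_delta = salt_delta, smoking_delta = smoking_delta,
         inactivity_delta = inactivity_delta, mix = mix),
    class = "chd_scenario"
  )
}

#' @rdname chd_scenario
#' @export
scenario_low_sfa <- function() {
  chd_scenario("low_sfa_10E", target_sfa = 10,
               baseline_sfa = c(male = 15.9, female = 14.4),
               salt_delta = -1, smoking_delta = -0.05,
               inactivity_delta = -0.05)
}

#' @rdname chd_scenario
#' @export
scenario_high_sfa <- function() {
  chd_scenario("high_sfa_20E", target_sfa = 20,
               baseline_sfa = c(male = 17.5, female = 16.0),
               salt_delta = -1, smoking_delta = -0.05,
               inactivity_delta = -0.05)
}

#' @rdname chd_scenario
#' @export
scenario_trend_only <- function() {
  chd_scenario("trend_only", target_sfa = NULL,
               salt_delta = -1, smoking_delta = -0.05,
               inactivity_delta = -0.05)
}

#' @rdname chd_scenario
#' @export
scenario_null <- function() chd_scenario("null")

# Align all per-stratum inputs into plain vectors ordered as chd_strata(),
# so the scenario core (and the Monte Carlo loop around it) is cheap.
scenario_context <- function(inputs, fits = NULL) {
  stopifnot(inherits(inputs, "chd_inputs") || is.list(inputs))
  if (is.null(fits)) fits <- fit_all_strata(inputs$series)
  strata <- chd_strata()
  key <- paste(strata$sex, strata$age_band)

  align <- function(tab, col) {
    tab <- assert_strata_complete(tab, col)
    idx <- match(key, paste(tab$sex, tab$age_band))
    tab[[col]][idx]
  }
  exp25 <- expected_deaths(fits, 2025, inputs$population_2025)
  list(
    strata = strata,
    sex = as.character(strata$sex),
    deaths_2010 = align(inputs$deaths_2010, "deaths"),
    expected_2025 = exp25$by_stratum$expected_deaths[
      match(key, paste(exp25$by_stratum$sex, exp25$by_stratum$age_band))],
    baseline_total_2025 = exp25$total,
    baseline_by_sex_2025 = exp25$by_sex,
    smoking_prev = align(inputs$risk_factors_2010, "smoking_prev"),
    inactivity_prev = align(inputs$risk_factors_2010, "inactivity_prev")
  )
}

# Parameter vectors aligned to chd_strata() order.
align_params <- function(params) {
  strata <- chd_strata()
  key <- paste(strata$sex, strata$age_band)
  grab <- function(tab, col) tab[[col]][match(key, paste(tab$sex, tab$age_band))]
  list(
    beta_chol = grab(params$beta_chol, "beta"),
    beta_sbp = grab(params$beta_sbp, "beta"),
    rr_smoking = grab(params$rr_smoking, "rr"),
    rr_inactivity = grab(params$rr_inactivity, "rr"),
    constants = params$constants
  )
}

# Fast core: per-stratum DPP for the four factors, returned as a list of
# numeric vectors in chd_strata() order. `pv` is an align_params() list.
scenario_dpp_core <- function(scenario, ctx, pv, form = "linear") {
  cst <- pv$constants
  # continuous factors: regression route on 2010 deaths
  if (is.null(scenario$target_sfa)) {
    delta_chol <- c(male = 0, female = 0)
  } else {
    delta_chol <- scenario_cholesterol_delta(
      scenario$baseline_sfa, scenario$target_sfa, mix = scenario$mix,
      params = list(constants = cst)
    )
  }
  delta_sbp <- salt_delta_to_sbp_delta(scenario$salt_delta,
                                       params = list(constants = cst))
  dpp_chol <- unname(dpp_regression(ctx$deaths_2010, delta_chol[ctx$sex],
                                    pv$beta_chol, form = form))
  dpp_sbp <- unname(dpp_regression(ctx$deaths_2010, delta_sbp, pv$beta_sbp,
                                   form = form))

  # binary factors: PARF-difference route on 2025 expected deaths
  shift_prev <- function(p, delta, factor_name) {
    p_new <- p + delta
    if (delta < 0) p_new <- pmax(p_new, 0)
    if (any(p_new > 1)) {
      bad <- which(p_new > 1)[1]
      stop("Scenario '", scenario$name, "' pushes ", factor_name,
           " prevalence above 1 in stratum ",
           ctx$sex[bad], " ", as.character(ctx$strata$age_band[bad]),
           call. = FALSE)
    }
    p_new
  }
  smk_new <- shift_prev(ctx$smoking_prev, scenario$smoking_delta, "smoking")
  ina_new <- shift_prev(ctx$inactivity_prev, scenario$inactivity_delta,
                        "inactivity")
  dpp_smk <- dpp_parf(ctx$expected_2025,
                      parf(ctx$smoking_prev, pv$rr_smoking),
                      parf(smk_new, pv$rr_smoking))
  dpp_ina <- dpp_parf(ctx$expected_2025,
                      parf(ctx$inactivity_prev, pv$rr_inactivity),
                      parf(ina_new, pv$rr_inactivity))
  list(cholesterol = dpp_chol, sbp = dpp_sbp, smoking = dpp_smk,
       inactivity = dpp_ina, delta_chol = delta_chol, delta_sbp = delta_sbp)
}

#' Run a full scenario through the DPP engine
#'
#' Computes deaths prevented or postponed (DPP) per stratum and per risk
#' factor for a scenario against the continued-decline baseline:
#' cholesterol and SBP contributions via the regression route on observed
#' 2010 deaths, smoking and inactivity via the PARF-difference route on
#' expected 2025 deaths. Totals are exact sums of unrounded parts;
#' reported values are additionally rounded to the nearest 5.
#'
#' @param scenario A [chd_scenario()].
#' @param inputs A `chd_inputs` bundle (see [synthetic_sweden()]), or any
#'   list providing `series`, `deaths_2010`, `population_2025`,
#'   `risk_factors_2010` and `params`.
#' @param fits Optional precomputed [fit_all_strata()] result; fitted from
#'   `inputs$series` when `NULL`.
#' @param params Effect parameters; defaults to `inputs$params`.
#' @param form Regression form for continuous factors, `"linear"`
#'   (default) or `"loglinear"`.
#' @return A list of class `dpp_result`: `results` (tidy tibble `scenario`,
#'   `sex`, `age_band`, `factor`, `dpp_raw`, `dpp_rounded`), `by_factor`,
#'   `by_sex`, `total_dpp`, `baseline_2025` (expected deaths with no
#'   risk-factor change), `net_2025` (`baseline_2025 - total_dpp`),
#'   `deltas` (the risk-factor changes applied), and `form`.
#' @export
run_scenario <- function(scenario, inputs, fits = NULL,
                         params = inputs$params,
                         form = c("linear", "loglinear")) {
  form <- match.arg(form)
  stopifnot(inherits(scenario, "chd_scenario"))
  ctx <- scenario_context(inputs, fits)
  pv <- align_params(params)
  core <- scenario_dpp_core(scenario, ctx, pv, form = form)

  factors <- c("cholesterol", "sbp", "smoking", "inactivity")
  results <- dplyr::bind_rows(lapply(factors, function(f) {
    tibble::tibble(scenario = scenario$name, sex = ctx$strata$sex,
                   age_band = ctx$strata$age_band, factor = f,
                   dpp_raw = core[[f]], dpp_rounded = round_to_5(core[[f]]))
  }))
  by_factor <- dplyr::summarise(
    dplyr::group_by(results, .data$factor, .data$sex),
    dpp_raw = sum(.data$dpp_raw), .groups = "drop")
  by_factor$dpp_rounded <- round_to_5(by_factor$dpp_raw)
  by_sex <- dplyr::summarise(dplyr::group_by(results, .data$sex),
                             dpp_raw = sum(.data$dpp_raw), .groups = "drop")
  by_sex$dpp_rounded <- round_to_5(by_sex$dpp_raw)
  total <- sum(results$dpp_raw)
  structure(
    list(
      scenario = scenario, results = results, by_factor = by_factor,
      by_sex = by_sex, total_dpp = total,
      baseline_2025 = ctx$baseline_total_2025,
      baseline_by_sex_2025 = ctx$baseline_by_sex_2025,
      net_2025 = ctx$baseline_total_2025 - total,
      deltas = list(cholesterol = core$delta_chol, sbp = core$delta_sbp,
                    salt = scenario$salt_delta,
                    smoking = scenario$smoking_delta,
                    inactivity = scenario$inactivity_delta),
      form = form
    ),
    class = "dpp_result"
  )
}

#' @export
print.dpp_result <- function(x, ...) {
  cat(sprintf("<dpp_result '%s' (%s form)>\n", x$scenario$name, x$form))
  cat(sprintf("  baseline expected deaths 2025: %.1f\n", x$baseline_2025))
  cat(sprintf("  total DPP: %.1f (rounded %d) = %.1f%% of baseline\n",
              x$total_dpp, as.integer(round_to_5(x$total_dpp)),
              100 * x$total_dpp / x$baseline_2025))
  cat(sprintf("  net expected deaths 2025: %.1f\n", x$net_2025))
  agg <- dplyr::summarise(dplyr::group_by(x$by_factor, .data$factor),
                          dpp = sum(.data$dpp_raw), .groups = "drop")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("    %-12s %8.1f (rounded %d)\n", agg$factor[i], agg$dpp[i],
                as.integer(round_to_5(agg$dpp[i]))))
  }
  invisible(x)
}
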