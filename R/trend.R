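#' Fit an exponential decay model to a stratum mortality series
#'
#' Models the age-specific CHD mortality rate as
#' `rate(t) = rate_ref * exp(-lambda * (t - ref_year))` and estimates
#' `lambda` by ordinary least squares on log rates (multiplicative error),
#' the default, or by Poisson regression of death counts with a log
#' population offset (`method = "poisson"`). The reference year is the last
#' observed year, so the fitted value there anchors forward projection.
#'
#' @param series Mortality series tibble for a single stratum with columns
#'   `year`, `deaths`, `population`, `rate` (see
#'   [generate_mortality_series()]).
#' @param method `"ols_log"` (default) or `"poisson"`.
#' @param continuity_correction If `TRUE`, 0.5 is added to the death count
#'   in years with zero deaths (only those years) before fitting. By
#'   default zero rates are an error, since silently correcting them
#'   changes the fit.
#' @return A list of class `trend_fit`: `sex`, `age_band`, `lambda`
#'   (per-year decline rate), `rate_ref` (fitted rate at `ref_year`),
#'   `ref_year`, `method`, and `diagnostics` (R-squared of the log-linear
#'   fit and residual summary).
#' @examples
#' s <- generate_mortality_series("male", "65-74", 2e-3, 0.04, rep(5e5, 25))
#' fit_exponential_decay(s)
#' @export
fit_exponential_decay <- function(series, method = c("ols_log", "poisson"),
                                  continuity_correction = FALSE) {
  method <- match.arg(method)
  if (nrow(series) < 3) {
    stop("At least 3 years of data are required to fit a trend", call. = FALSE)
  }
  if (any(diff(series$year) <= 0)) {
    stop("years must be strictly increasing", call. = FALSE)
  }
  deaths <- series$deaths
  if (any(deaths == 0)) {
    if (!continuity_correction) {
      stop("Zero death counts in year(s) ",
           paste(series$year[deaths == 0], collapse = ", "),
           ": log rates are undefined. Re-run with ",
           "continuity_correction = TRUE to add 0.5 deaths in those years ",
           "only.", call. = FALSE)
    }
    deaths[deaths == 0] <- 0.5
  }
  rate <- deaths / series$population
  ref_year <- max(series$year)
  x <- series$year - ref_year

  if (method == "ols_log") {
    fit <- stats::lm(log(rate) ~ x)
    lambda <- -unname(stats::coef(fit)[2])
    rate_ref <- exp(unname(stats::coef(fit)[1]))
    resid <- stats::resid(fit)
    tss <- sum((log(rate) - mean(log(rate)))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(resid^2) / tss
  } else {
    fit <- stats::glm(deaths ~ x, offset = log(series$population),
                      family = stats::poisson())
    lambda <- -unname(stats::coef(fit)[2])
    rate_ref <- exp(unname(stats::coef(fit)[1]))
    # R^2 on the log-rate scale for comparability across methods
    lr <- log(rate)
    r2 <- 1 - sum((lr - (log(rate_ref) - lambda * x))^2) / sum((lr - mean(lr))^2)
    resid <- stats::resid(fit, type = "deviance")
  }
  structure(
    list(
      sex = if ("sex" %in% names(series)) as.character(series$sex[1]) else NA_character_,
      age_band = if ("age_band" %in% names(series)) as.character(series$age_band[1]) else NA_character_,
      lambda = lambda, rate_ref = rate_ref, ref_year = ref_year,
      method = method,
      diagnostics = list(r_squared = r2,
                         resid_summary = summary(unname(resid)))
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit %s %s> lambda=%.4f/yr rate(%d)=%.3g R2=%.3f (%s)\n",
              x$sex, x$age_band, x$lambda, x$ref_year, x$rate_ref,
              x$diagnostics$r_squared, x$method))
  invisible(x)
}

#' Project a fitted mortality rate to a calendar year
#'
#' @param fit A `trend_fit` from [fit_exponential_decay()].
#' @param year Calendar year(s); the closed form
#'   `rate_ref * exp(-lambda * (year - ref_year))` is evaluated as given,
#'   so years before `ref_year` recover the fitted historical curve.
#' @return Per-capita rate(s).
#' @export
project_rate <- function(fit, year) {
  stopifnot(inherits(fit, "trend_fit"))
  fit$rate_ref * exp(-fit$lambda * (year - fit$ref_year))
}

#' Fit trends for every stratum of a combined mortality series
#'
#' @param series Long mortality series covering all 12 strata.
#' @inheritParams fit_exponential_decay
#' @return A named list of `trend_fit` objects (names `"sex age_band"`),
#'   of class `trend_fits`.
#' @export
fit_all_strata <- function(series, method = c("ols_log", "poisson"),
                           continuity_correction = FALSE) {
  method <- match.arg(method)
  series <- normalise_strata(series)
  strata <- chd_strata()
  fits <- vector("list", nrow(strata))
  names(fits) <- paste(strata$sex, strata$age_band)
  for (i in seq_len(nrow(strata))) {
    sub <- series[series$sex == strata$sex[i] &
                    series$age_band == strata$age_band[i], ]
    if (nrow(sub) == 0) {
      stop("No mortality series for stratum ", names(fits)[i], call. = FALSE)
    }
    fits[[i]] <- fit_exponential_decay(sub[order(sub$year), ], method = method,
                                       continuity_correction = continuity_correction)
  }
  structure(fits, class = "trend_fits")
}

#' Expected CHD deaths in a projection year
#'
#' Multiplies each stratum's projected mortality rate by its projected
#' population and sums. With `constant_rate = TRUE` the stratum rates are
#' frozen at their fitted reference-year values (lambda treated as 0),
#' giving the constant-rate counterfactual against which the continued
#' decline is compared.
#'
#' @param fits A `trend_fits` list covering all 12 strata.
#' @param year Projection year.
#' @param population Tibble `sex`, `age_band`, `population` (optionally
#'   `year`, filtered to `year` if present) for all strata.
#' @param constant_rate Freeze rates at the reference year?
#' @return A list of class `expected_deaths`: `by_stratum` tibble (`sex`,
#'   `age_band`, `year`, `rate`, `population`, `expected_deaths`),
#'   `by_sex`, and `total` (exact sums, no rounding).
#' @export
expected_deaths <- function(fits, year, population, constant_rate = FALSE) {
  stopifnot(inherits(fits, "trend_fits"))
  if ("year" %in% names(population)) {
    population <- population[population$year == year, ]
  }
  population <- assert_strata_complete(population, "population projection")
  if (any(population$population <= 0)) {
    stop("populations must be positive", call. = FALSE)
  }
  strata <- chd_strata()
  missing <- setdiff(paste(strata$sex, strata$age_band), names(fits))
  if (length(missing) > 0) {
    stop("Trend fits missing for strata: ", paste(missing, collapse = "; "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    key <- paste(strata$sex[i], strata$age_band[i])
    fit <- fits[[key]]
    rate <- if (constant_rate) fit$rate_ref else project_rate(fit, year)
    pop <- population$population[population$sex == strata$sex[i] &
                                   population$age_band == strata$age_band[i]]
    tibble::tibble(sex = strata$sex[i], age_band = strata$age_band[i],
                   year = year, rate = rate, population = pop,
                   expected_deaths = rate * pop)
  })
  by_stratum <- dplyr::bind_rows(rows)
  by_sex <- dplyr::summarise(dplyr::group_by(by_stratum, .data$sex),
                             expected_deaths = sum(.data$expected_deaths),
                             .groups = "drop")
  structure(
    list(by_stratum = by_stratum, by_sex = by_sex,
         total = sum(by_stratum$expected_deaths), year = year,
         constant_rate = constant_rate),
    class = "expected_deaths"
  )
}

#' @export
print.expected_deaths <- function(x, ...) {
  kind <- if (x$constant_rate) "constant-rate counterfactual" else "projected"
  cat(sprintf("<expected_deaths %d, %s> total %.1f (%s)\n", x$year, kind,
              x$total,
              paste(sprintf("%s %.1f", x$by_sex$sex, x$by_sex$expected_deaths),
                    collapse = ", ")))
  invisible(x)
}
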