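#' Generate a synthetic age-specific CHD mortality series
#'
#' Emulates the statistical structure the trend model assumes: an
#' age-specific per-capita CHD mortality rate declining exponentially from
#' a 1986 level, with death counts either deterministic (expected counts,
#' rounded) or drawn from a Poisson distribution with the expected count as
#' mean.
#'
#' @param sex,age_band Stratum labels (see [chd_strata()]).
#' @param rate_1986 Per-capita mortality rate in the first year; > 0.
#' @param decay Exponential decline rate per year (lambda >= 0); the
#'   expected rate in year `t` is `rate_1986 * exp(-decay * (t - years[1]))`.
#' @param population Positive population counts, one per year.
#' @param years Calendar years, strictly increasing; default 1986-2010.
#' @param noise `"none"` for deterministic rounded counts, `"poisson"` for
#'   Poisson-distributed counts.
#' @param seed Optional integer seed (required for reproducible
#'   `"poisson"` draws); the generator leaves the global RNG state
#'   untouched.
#' @return A tibble with columns `sex`, `age_band`, `year`, `population`,
#'   `deaths` and `rate` (`deaths / population`).
#' @examples
#' pop <- rep(500000, 25)
#' generate_mortality_series("male", "65-74", 2e-3, 0.04, pop)
#' @export
generate_mortality_series <- function(sex, age_band, rate_1986, decay,
                                      population, years = 1986:2010,
                                      noise = c("none", "poisson"),
                                      seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(rate_1986) == 1, length(decay) == 1)
  if (rate_1986 <= 0) stop("rate_1986 must be positive", call. = FALSE)
  if (decay < 0) {
    stop("decay must be >= 0: the baseline trend is a decay model",
         call. = FALSE)
  }
  if (any(population <= 0)) stop("populations must be positive", call. = FALSE)
  if (length(population) != length(years)) {
    stop("population must have one value per year", call. = FALSE)
  }
  if (any(diff(years) <= 0)) stop("years must be strictly increasing", call. = FALSE)

  mu <- rate_1986 * exp(-decay * (years - years[1])) * population
  deaths <- switch(noise,
    none = round(mu),
    poisson = {
      if (is.null(seed)) stop("seed is required for poisson noise", call. = FALSE)
      with_local_seed(seed, stats::rpois(length(mu), mu))
    }
  )
  normalise_strata(tibble::tibble(
    sex = sex, age_band = age_band, year = as.integer(years),
    population = as.numeric(population), deaths = as.numeric(deaths),
    rate = deaths / population
  ))
}

#' Generate synthetic mortality series for all strata
#'
#' Applies [generate_mortality_series()] across a table of per-stratum
#' baseline rates and decay parameters (by default the packaged calibrated
#' stand-in for the Swedish registry series, [synthetic_baseline_rates()]).
#'
#' @param baseline Tibble with columns `sex`, `age_band`, `rate_1986`,
#'   `lambda` for all 12 strata.
#' @param population Long tibble `sex`, `age_band`, `year`, `population`
#'   covering the observation years.
#' @param years Observation years.
#' @inheritParams generate_mortality_series
#' @return Row-bound mortality series for all strata.
#' @export
generate_all_mortality_series <- function(baseline = synthetic_baseline_rates(),
                                          population = synthetic_population(),
                                          years = 1986:2010,
                                          noise = c("none", "poisson"),
                                          seed = NULL) {
  noise <- match.arg(noise)
  assert_strata_complete(baseline, "baseline rate table")
  strata <- chd_strata()
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    s <- as.character(strata$sex[i]); a <- as.character(strata$age_band[i])
    b <- baseline[baseline$sex == s & baseline$age_band == a, ]
    pop <- population[population$sex == s & population$age_band == a &
                        population$year %in% years, ]
    pop <- pop[order(pop$year), ]
    out[[i]] <- generate_mortality_series(
      s, a, b$rate_1986, b$lambda, pop$population, years = sort(pop$year),
      noise = noise,
      seed = if (is.null(seed)) NULL else seed + i
    )
  }
  dplyr::bind_rows(out)
}

#' Packaged synthetic baseline inputs
#'
#' Calibrated stand-ins for the registry inputs the model needs: a
#' per-stratum 1986 CHD mortality rate and exponential decline rate
#' (`synthetic_baseline_rates()`), and population counts by stratum for
#' 1986-2010 plus the 2025 official-style projection
#' (`synthetic_population()`). Values are synthetic: they are constructed
#' to have realistic age/sex structure and to reproduce the published
#' headline magnitudes (about 5,975 expected CHD deaths in 2025 under
#' continued decline versus about 11,000 under constant 2010 rates), not
#' taken from any registry extract.
#'
#' @return A tibble (see Details).
#' @export
synthetic_baseline_rates <- function() {
  path <- system.file("extdata", "synthetic_baseline_rates.csv",
                      package = "chdimpact", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  normalise_strata(out)
}

#' @rdname synthetic_baseline_rates
#' @export
synthetic_population <- function() {
  path <- system.file("extdata", "synthetic_population.csv",
                      package = "chdimpact", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  normalise_strata(out)
}

#' Effect parameters: stratum-specific coefficients and translation constants
#'
#' Bundles everything that converts risk-factor changes into mortality
#' changes:
#' \describe{
#'   \item{beta_chol}{per-stratum relative CHD mortality change per
#'     1 mmol/L total cholesterol (positive = higher cholesterol, higher
#'     mortality), with standard error.}
#'   \item{beta_sbp}{same, per 1 mm Hg systolic blood pressure.}
#'   \item{rr_smoking, rr_inactivity}{per-stratum relative risks (> 1) with
#'     95% CI, for the population attributable risk fraction route.}
#'   \item{constants}{fixed translation constants: `clarke_pufa` (0.078
#'     mmol/L cholesterol per 1 E% SFA replaced by polyunsaturated fat),
#'     `clarke_mufa` (0.048, monounsaturated), `salt_sbp_hyp` (7.2 mm Hg
#'     SBP per 6 g/day salt in hypertensives), `salt_sbp_norm` (3.6,
#'     normotensives), `hyp_prev` (0.37, population hypertension
#'     prevalence, held constant over the projection).}
#' }
#'
#' `default_effect_parameters()` loads the packaged calibrated synthetic
#' stand-in coefficient set; `generate_effect_parameters()` draws a random
#' plausible set around it (betas jittered on the log scale and re-sorted
#' so magnitudes decrease with age; relative risks jittered on the
#' log-excess-risk scale so they stay above 1). The translation constants
#' are never sampled at generation time.
#'
#' @param seed Integer seed; identical seeds give identical parameter sets.
#' @param scale Plausibility preset controlling jitter size.
#' @return A list of class `effect_parameters`.
#' @export
generate_effect_parameters <- function(seed, scale = c("default", "wide")) {
  scale <- match.arg(scale)
  sd <- switch(scale, default = 0.15, wide = 0.30)
  base <- default_effect_parameters()
  with_local_seed(seed, {
    jitter_beta <- function(tab) {
      tab$beta <- tab$beta * exp(stats::rnorm(nrow(tab), 0, sd))
      # enforce the documented convention: magnitude decreasing with age
      tab <- dplyr::group_by(tab, .data$sex)
      tab <- dplyr::mutate(tab, beta = sort(.data$beta, decreasing = TRUE))
      tab <- dplyr::ungroup(tab)
      tab$se <- 0.15 * tab$beta
      tab
    }
    jitter_rr <- function(tab) {
      tab$rr <- 1 + (tab$rr - 1) * exp(stats::rnorm(nrow(tab), 0, sd))
      tab$ci_low <- 1 + (tab$rr - 1) * exp(-1.96 * 0.12)
      tab$ci_high <- 1 + (tab$rr - 1) * exp(1.96 * 0.12)
      tab
    }
    out <- base
    out$beta_chol <- jitter_beta(base$beta_chol)
    out$beta_sbp <- jitter_beta(base$beta_sbp)
    out$rr_smoking <- jitter_rr(base$rr_smoking)
    out$rr_inactivity <- jitter_rr(base$rr_inactivity)
    out
  })
}

#' @rdname generate_effect_parameters
#' @export
default_effect_parameters <- function() {
  path <- system.file("extdata", "synthetic_effect_parameters.csv",
                      package = "chdimpact", mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pick <- function(p) {
    out <- raw[raw$param == p, c("sex", "age_band", "value", "spread")]
    normalise_strata(out)
  }
  beta_chol <- pick("beta_chol"); names(beta_chol)[3:4] <- c("beta", "se")
  beta_sbp <- pick("beta_sbp"); names(beta_sbp)[3:4] <- c("beta", "se")
  as_rr <- function(p) {
    tab <- pick(p); names(tab)[3:4] <- c("rr", "log_excess_sd")
    tab$ci_low <- 1 + (tab$rr - 1) * exp(-1.96 * tab$log_excess_sd)
    tab$ci_high <- 1 + (tab$rr - 1) * exp(1.96 * tab$log_excess_sd)
    tab[, c("sex", "age_band", "rr", "ci_low", "ci_high")]
  }
  effect_parameters(
    beta_chol = beta_chol, beta_sbp = beta_sbp,
    rr_smoking = as_rr("rr_smoking"), rr_inactivity = as_rr("rr_inactivity")
  )
}

#' @rdname generate_effect_parameters
#' @param beta_chol,beta_sbp Tibbles `sex`, `age_band`, `beta`, `se`.
#' @param rr_smoking,rr_inactivity Tibbles `sex`, `age_band`, `rr`,
#'   `ci_low`, `ci_high`.
#' @param clarke_pufa,clarke_mufa,salt_sbp_hyp,salt_sbp_norm,hyp_prev
#'   Translation constants (see Description for defaults).
#' @export
effect_parameters <- function(beta_chol, beta_sbp, rr_smoking, rr_inactivity,
                              clarke_pufa = 0.078, clarke_mufa = 0.048,
                              salt_sbp_hyp = 7.2, salt_sbp_norm = 3.6,
                              hyp_prev = 0.37) {
  for (tab in list(beta_chol, beta_sbp)) {
    assert_strata_complete(tab, "beta coefficient table")
    if (any(tab$se < 0)) stop("standard errors must be >= 0", call. = FALSE)
  }
  for (tab in list(rr_smoking, rr_inactivity)) {
    assert_strata_complete(tab, "relative risk table")
    if (any(tab$rr < 0)) stop("relative risks must be >= 0", call. = FALSE)
  }
  if (hyp_prev < 0 || hyp_prev > 1) {
    stop("hyp_prev must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      beta_chol = normalise_strata(beta_chol),
      beta_sbp = normalise_strata(beta_sbp),
      rr_smoking = normalise_strata(rr_smoking),
      rr_inactivity = normalise_strata(rr_inactivity),
      constants = list(
        clarke_pufa = clarke_pufa, clarke_mufa = clarke_mufa,
        salt_sbp_hyp = salt_sbp_hyp, salt_sbp_norm = salt_sbp_norm,
        hyp_prev = hyp_prev
      )
    ),
    class = "effect_parameters"
  )
}

#' @export
print.effect_parameters <- function(x, ...) {
  cat("<effect_parameters>\n")
  cat("  beta_chol: per 1 mmol/L, range",
      sprintf("%.3f-%.3f", min(x$beta_chol$beta), max(x$beta_chol$beta)), "\n")
  cat("  beta_sbp:  per 1 mm Hg, range",
      sprintf("%.4f-%.4f", min(x$beta_sbp$beta), max(x$beta_sbp$beta)), "\n")
  cat("  rr_smoking range",
      sprintf("%.2f-%.2f", min(x$rr_smoking$rr), max(x$rr_smoking$rr)), "\n")
  cat("  rr_inactivity range",
      sprintf("%.2f-%.2f", min(x$rr_inactivity$rr), max(x$rr_inactivity$rr)), "\n")
  cst <- x$constants
  cat(sprintf("  constants: clarke_pufa=%.3f clarke_mufa=%.3f salt_hyp=%.1f salt_norm=%.1f hyp_prev=%.2f\n",
              cst$clarke_pufa, cst$clarke_mufa, cst$salt_sbp_hyp,
              cst$salt_sbp_norm, cst$hyp_prev))
  invisible(x)
}

#' Assemble the full synthetic study input bundle
#'
#' Convenience constructor for everything a scenario run needs: the
#' synthetic mortality series (1986-2010), 2010 observed deaths by stratum,
#' the 2025 population projection, the 2010 risk-factor profile, the diet
#' profile, and effect parameters.
#'
#' @param seed Optional seed; when supplied, mortality counts are Poisson
#'   and effect parameters are drawn with [generate_effect_parameters()].
#'   When `NULL` (default), counts are deterministic expected values and
#'   the calibrated default parameters are used.
#' @return A list of class `chd_inputs` with elements `series`,
#'   `deaths_2010`, `population_2025`, `risk_factors_2010`, `diet`,
#'   `params`.
#' @export
synthetic_sweden <- function(seed = NULL) {
  series <- generate_all_mortality_series(
    noise = if (is.null(seed)) "none" else "poisson",
    seed = seed
  )
  pop <- synthetic_population()
  deaths_2010 <- series[series$year == 2010,
                        c("sex", "age_band", "population", "deaths")]
  params <- if (is.null(seed)) {
    default_effect_parameters()
  } else {
    generate_effect_parameters(seed + 1000L)
  }
  structure(
    list(
      series = series,
      deaths_2010 = deaths_2010,
      population_2025 = pop[pop$year == 2025, ],
      risk_factors_2010 = swedish_risk_factors(2010)$by_stratum,
      diet = diet_profile(),
      params = params
    ),
    class = "chd_inputs"
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
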