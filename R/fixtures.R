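#' Swedish population risk-factor levels (survey fixtures)
#'
#' Published population-level risk-factor estimates for Sweden, as used to
#' parameterise the projection model: sex-specific national means for 1986,
#' 2002 and 2010, and the full sex-by-age-band breakdown for 2010.
#' National 2010 cholesterol and blood-pressure means combine a northern
#' cohort (15% weight) and a southern cohort (85% weight) to reflect the
#' national population distribution; see [weighted_national_mean()].
#'
#' @param year Survey year; one of 1986, 2002 or 2010. The by-stratum
#'   breakdown exists only for 2010.
#' @return A list with elements:
#'   \describe{
#'     \item{overall}{tibble, one row per sex: `sex`, `year`, `chol_mean`
#'       (total cholesterol, mmol/L), `sbp_mean` (mm Hg), `smoking_prev`,
#'       `inactivity_prev`, `diabetes_prev` (fractions in \[0,1\]),
#'       `bmi_mean` (kg/m^2). Diabetes and BMI are carried for context but
#'       are not model terms.}
#'     \item{by_stratum}{for 2010, a 12-row tibble with the same measure
#'       columns plus `age_band`; `NULL` for 1986 and 2002.}
#'   }
#' @examples
#' swedish_risk_factors(2010)$overall
#' @export
swedish_risk_factors <- function(year) {
  if (length(year) != 1 || !year %in% c(1986, 2002, 2010)) {
    stop("No risk-factor fixture for year ", paste(year, collapse = ","),
         "; available fixtures: 1986, 2002, 2010", call. = FALSE)
  }
  overall <- risk_factor_overall_table()
  overall <- overall[overall$year == year, , drop = FALSE]
  by_stratum <- if (year == 2010) risk_factor_2010_table() else NULL
  list(overall = overall, by_stratum = by_stratum)
}

# Sex-level national means, 1986 / 2002 / 2010. Prevalences are stored as
# fractions, not percent.
risk_factor_overall_table <- function() {
  out <- tibble::tribble(
    ~sex,     ~year, ~chol_mean, ~smoking_prev, ~sbp_mean, ~diabetes_prev, ~bmi_mean, ~inactivity_prev,
    "male",    1986,       6.15,         0.313,     135.0,          0.028,      24.8,            0.159,
    "male",    2002,       5.51,         0.176,     132.9,          0.042,      26.0,            0.127,
    "male",    2010,       5.48,         0.132,     134.3,          0.067,      26.3,            0.173,
    "female",  1986,       6.19,         0.266,     132.7,          0.025,      23.8,            0.156,
    "female",  2002,       5.51,         0.195,     129.7,          0.034,      24.8,            0.104,
    "female",  2010,       5.53,         0.152,     130.8,          0.051,      24.9,            0.120
  )
  out$sex <- factor(out$sex, levels = sex_levels())
  out
}

# 2010 levels by sex and 10-year age band.
risk_factor_2010_table <- function() {
  male <- tibble::tibble(
    sex = "male",
    age_band = age_band_levels(),
    chol_mean = c(4.98, 5.36, 5.48, 5.56, 5.57, 5.48),
    smoking_prev = c(11.8, 10.5, 13.8, 18.1, 15.8, 6.0) / 100,
    sbp_mean = c(125.9, 126.4, 131.7, 139.2, 145.4, 151.3),
    diabetes_prev = c(0.9, 1.8, 4.3, 9.4, 15.2, 18.0) / 100,
    bmi_mean = c(25.5, 26.7, 26.7, 26.6, 26.5, 25.6),
    inactivity_prev = c(11.4, 20.0, 19.7, 18.7, 14.8, 20.9) / 100
  )
  female <- tibble::tibble(
    sex = "female",
    age_band = age_band_levels(),
    chol_mean = c(4.66, 4.92, 5.51, 5.51, 5.80, 5.68),
    smoking_prev = c(11.3, 14.3, 24.2, 16.7, 13.3, 6.3) / 100,
    sbp_mean = c(118.3, 119.1, 126.5, 136.9, 144.2, 153.3),
    diabetes_prev = c(0.8, 1.4, 2.9, 5.9, 10.4, 14.1) / 100,
    bmi_mean = c(23.6, 24.5, 25.4, 25.3, 25.8, 25.2),
    inactivity_prev = c(9.0, 12.8, 10.6, 9.9, 12.0, 23.3) / 100
  )
  normalise_strata(dplyr::bind_rows(male, female))
}

#' Combine regional survey estimates into a national mean
#'
#' National risk-factor levels are formed as a population-weighted average
#' of a northern and a southern survey estimate (default weights 15% north,
#' 85% south).
#'
#' @param north_value,south_value Regional estimates (same units).
#' @param w_north,w_south Non-negative weights summing to 1.
#' @return `w_north * north_value + w_south * south_value`.
#' @examples
#' weighted_national_mean(6.0, 5.0)  # 0.15 north / 0.85 south
#' @export
weighted_national_mean <- function(north_value, south_value,
                                   w_north = 0.15, w_south = 0.85) {
  if (w_north < 0 || w_south < 0) {
    stop("Weights must be non-negative", call. = FALSE)
  }
  if (abs(w_north + w_south - 1) > 1e-9) {
    stop("Weights must sum to 1 (got ", w_north + w_south, ")", call. = FALSE)
  }
  w_north * north_value + w_south * south_value
}

#' Dietary intake profile
#'
#' Mean dietary fat intake as percent of total energy (E%) by fatty-acid
#' class, plus mean salt intake in g/day. The default salt intake of
#' 10 g/day is the national survey estimate across all age groups and both
#' sexes; the default fat profile reflects northern-cohort survey levels in
#' the early 2010s.
#'
#' @param sfa_e,mufa_e,pufa_e Energy percent from saturated, monounsaturated
#'   and polyunsaturated fat.
#' @param salt Salt intake, g/day.
#' @return A one-row tibble of class `diet_profile`.
#' @export
diet_profile <- function(sfa_e = 16.7, mufa_e = 13.5, pufa_e = 5.5,
                         salt = 10) {
  vals <- c(sfa_e = sfa_e, mufa_e = mufa_e, pufa_e = pufa_e, salt = salt)
  if (any(vals < 0)) stop("Diet profile values must be non-negative", call. = FALSE)
  if (sfa_e + mufa_e + pufa_e > 100) {
    stop("Total fat E% cannot exceed 100", call. = FALSE)
  }
  out <- tibble::tibble(sfa_e = sfa_e, mufa_e = mufa_e, pufa_e = pufa_e,
                        salt = salt)
  class(out) <- c("diet_profile", class(out))
  out
}
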