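#' Isocaloric fat replacement mix
#'
#' When saturated fat intake changes, the displaced (or displacing) energy
#' is assumed to be exchanged with unsaturated fat in fixed proportions.
#' The default is 90% polyunsaturated / 10% monounsaturated.
#'
#' @param frac_pufa,frac_mufa Fractions in \[0,1\] summing to 1.
#' @return A named list of class `replacement_mix`.
#' @export
replacement_mix <- function(frac_pufa = 0.90, frac_mufa = 0.10) {
  if (frac_pufa < 0 || frac_pufa > 1 || frac_mufa < 0 || frac_mufa > 1) {
    stop("Mix fractions must be in [0, 1]", call. = FALSE)
  }
  if (abs(frac_pufa + frac_mufa - 1) > 1e-9) {
    stop("Mix fractions must sum to 1 (got ", frac_pufa + frac_mufa, ")",
         call. = FALSE)
  }
  structure(list(frac_pufa = frac_pufa, frac_mufa = frac_mufa),
            class = "replacement_mix")
}

#' Translate a saturated-fat intake change into a total-cholesterol change
#'
#' Applies the metaregression coefficients for isocaloric replacement of
#' saturated fat: each 1 E% of saturated fat replaced by polyunsaturated
#' fat lowers total cholesterol by 0.078 mmol/L, and by monounsaturated fat
#' by 0.048 mmol/L. With the default 90/10 replacement mix the combined
#' effect is 0.075 mmol/L per E%. The relationship is linear and
#' sign-preserving; it is considered reliable for saturated-fat intakes in
#' the 10-20 E% range.
#'
#' @param delta_sfa Signed change in saturated-fat intake, E%.
#' @param mix A [replacement_mix()].
#' @param params An `effect_parameters` bundle (only the Clarke constants
#'   are used).
#' @return Signed total-cholesterol change, mmol/L.
#' @examples
#' sfa_delta_to_cholesterol_delta(-1)   # -0.075 mmol/L
#' @export
sfa_delta_to_cholesterol_delta <- function(delta_sfa, mix = replacement_mix(),
                                           params = default_effect_parameters()) {
  stopifnot(inherits(mix, "replacement_mix"))
  cst <- params$constants
  per_e_pct <- cst$clarke_pufa * mix$frac_pufa + cst$clarke_mufa * mix$frac_mufa
  delta_sfa * per_e_pct
}

#' Translate a salt intake change into a systolic blood pressure change
#'
#' A 6 g/day salt reduction lowers SBP by 7.2 mm Hg in hypertensives and
#' 3.6 mm Hg in normotensives; the population effect is the
#' hypertension-prevalence-weighted average, linear in the salt change.
#' At the default 37% hypertension prevalence a 1 g/day reduction gives
#' -0.822 mm Hg.
#'
#' @param delta_salt Signed change in salt intake, g/day.
#' @param params An `effect_parameters` bundle (salt constants and
#'   `hyp_prev` are used).
#' @return Signed SBP change, mm Hg.
#' @examples
#' salt_delta_to_sbp_delta(-1)   # -0.822 mm Hg
#' @export
salt_delta_to_sbp_delta <- function(delta_salt,
                                    params = default_effect_parameters()) {
  cst <- params$constants
  if (cst$hyp_prev < 0 || cst$hyp_prev > 1) {
    stop("hyp_prev must be in [0, 1]", call. = FALSE)
  }
  per_g <- (cst$salt_sbp_hyp * cst$hyp_prev +
              cst$salt_sbp_norm * (1 - cst$hyp_prev)) / 6
  delta_salt * per_g
}

#' Per-sex cholesterol change implied by a target saturated-fat intake
#'
#' Applies [sfa_delta_to_cholesterol_delta()] to the difference between a
#' sex-specific baseline saturated-fat intake and a common target intake.
#' A warning is issued when baseline or target lie outside the 10-20 E%
#' range in which the linear translation is considered reliable.
#'
#' @param baseline_sfa Named numeric, baseline intake (E%) per sex, names
#'   `"male"` and `"female"`.
#' @param target_sfa Target intake, E%.
#' @inheritParams sfa_delta_to_cholesterol_delta
#' @return Named numeric: signed cholesterol change (mmol/L) per sex.
#' @examples
#' scenario_cholesterol_delta(c(male = 15.9, female = 14.4), 10)
#' @export
scenario_cholesterol_delta <- function(baseline_sfa, target_sfa,
                                       mix = replacement_mix(),
                                       params = default_effect_parameters()) {
  if (!all(sex_levels() %in% names(baseline_sfa))) {
    stop("baseline_sfa must be named with ",
         paste(sex_levels(), collapse = " and "), call. = FALSE)
  }
  vals <- c(baseline_sfa, target_sfa)
  if (any(vals <= 0) || any(vals >= 40)) {
    stop("Saturated-fat intakes must lie in (0, 40) E%", call. = FALSE)
  }
  if (any(vals < 10) || any(vals > 20)) {
    warning("Saturated-fat intake outside 10-20 E%: the linear ",
            "cholesterol translation is extrapolating beyond its ",
            "supported range", call. = FALSE)
  }
  out <- vapply(sex_levels(), function(s) {
    sfa_delta_to_cholesterol_delta(target_sfa - baseline_sfa[[s]],
                                   mix = mix, params = params)
  }, numeric(1))
  names(out) <- sex_levels()
  out
}
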