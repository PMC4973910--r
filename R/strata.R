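#' Population strata used throughout the model
#'
#' The model operates on 12 strata: sex crossed with closed 10-year age
#' bands covering ages 25-84. Every input table (mortality series, risk
#' factors, effect parameters, population projections) is indexed by these
#' strata, and most functions validate completeness against them.
#'
#' @return A tibble with columns `sex` (factor: `"male"`, `"female"`) and
#'   `age_band` (factor: `"25-34"` ... `"75-84"`), one row per stratum.
#' @examples
#' chd_strata()
#' @export
chd_strata <- function() {
  tidyr::expand_grid(
    sex = factor(c("male", "female"), levels = sex_levels()),
    age_band = factor(age_band_levels(), levels = age_band_levels())
  )
}

#' @rdname chd_strata
#' @export
age_band_levels <- function() {
  c("25-34", "35-44", "45-54", "55-64", "65-74", "75-84")
}

#' @rdname chd_strata
#' @export
sex_levels <- function() c("male", "female")

# Coerce sex / age_band columns to the canonical factor levels, erroring on
# unknown labels.
normalise_strata <- function(df) {
  bad_sex <- setdiff(unique(as.character(df$sex)), sex_levels())
  if (length(bad_sex) > 0) {
    stop("Unknown sex label(s): ", paste(bad_sex, collapse = ", "),
         ". Expected one of: ", paste(sex_levels(), collapse = ", "),
         call. = FALSE)
  }
  bad_age <- setdiff(unique(as.character(df$age_band)), age_band_levels())
  if (length(bad_age) > 0) {
    stop("Unknown age band(s): ", paste(bad_age, collapse = ", "),
         ". Expected one of: ", paste(age_band_levels(), collapse = ", "),
         call. = FALSE)
  }
  df$sex <- factor(as.character(df$sex), levels = sex_levels())
  df$age_band <- factor(as.character(df$age_band), levels = age_band_levels())
  df
}

# Assert that `df` contains each of the 12 strata exactly once (per group
# defined by any extra key columns already handled by the caller).
assert_strata_complete <- function(df, what = "input") {
  df <- normalise_strata(df)
  have <- paste(df$sex, df$age_band)
  want <- with(chd_strata(), paste(sex, age_band))
  missing <- setdiff(want, have)
  if (length(missing) > 0) {
    stop(what, " is missing strata: ", paste(missing, collapse = "; "),
         call. = FALSE)
  }
  dup <- unique(have[duplicated(have)])
  if (length(dup) > 0) {
    stop(what, " has duplicated strata: ", paste(dup, collapse = "; "),
         call. = FALSE)
  }
  invisible(df)
}
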