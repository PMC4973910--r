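# Shared fixtures: the deterministic packaged input bundle and its trend
# fits, built once per test run. All other fixtures are built inline in the
# tests that need them.
default_inputs <- synthetic_sweden()
default_fits <- fit_all_strata(default_inputs$series)

# A minimal single-stratum mortality series following an exact exponential
# decay (no noise, unrounded counts) for closed-form checks.
exact_series <- function(rate0 = 0.01, lambda = 0.03, years = 1986:2010,
                         pop = 1e6) {
  rate <- rate0 * exp(-lambda * (years - years[1]))
  tibble::tibble(sex = "male", age_band = "65-74", year = years,
                 population = pop, deaths = rate * pop, rate = rate)
}
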