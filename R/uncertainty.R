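#' Declare a sampling distribution for a model parameter
#'
#' Each distribution targets one scalar inside an `effect_parameters`
#' bundle, addressed by path: `"beta_chol/male/45-54"`,
#' `"rr_smoking/female/65-74"`, or `"constants/hyp_prev"`.
#'
#' Families:
#' \describe{
#'   \item{normal}{draws `Normal(location, scale)` on the documented
#'     parameter scale.}
#'   \item{lognormal}{median-preserving multiplicative noise,
#'     `shift + (location - shift) * exp(Normal(0, scale))`. With the
#'     default `shift = 0` draws stay positive; with `shift = 1` (used for
#'     relative risks) the excess risk is lognormal and draws stay above
#'     1.}
#'   \item{point}{degenerate: always `location` (`scale` must be 0).}
#' }
#'
#' @param target Parameter path (see Description).
#' @param family `"normal"`, `"lognormal"` or `"point"`.
#' @param location Central value on the documented scale.
#' @param scale Spread (standard deviation; log-scale sd for lognormal);
#'   >= 0.
#' @param shift Lower bound for the lognormal family (default 0).
#' @return A list of class `param_dist`.
#' @export
param_dist <- function(target, family = c("normal", "lognormal", "point"),
                       location, scale = 0, shift = 0) {
  family <- match.arg(family)
  if (scale < 0) stop("scale must be >= 0", call. = FALSE)
  if (family == "point" && scale != 0) {
    stop("point distributions must have zero scale", call. = FALSE)
  }
  structure(list(target = target, family = family, location = location,
                 scale = scale, shift = shift),
            class = "param_dist")
}

# n draws from a param_dist.
draw_param <- function(dist, n = 1) {
  switch(dist$family,
    point = rep(dist$location, n),
    normal = stats::rnorm(n, dist$location, dist$scale),
    lognormal = dist$shift +
      (dist$location - dist$shift) * exp(stats::rnorm(n, 0, dist$scale))
  )
}

# Resolve a parameter path into getter/setter pieces; errors on unknown
# targets.
resolve_target <- function(params, target) {
  parts <- strsplit(target, "/", fixed = TRUE)[[1]]
  if (parts[1] == "constants") {
    if (length(parts) != 2 || !parts[2] %in% names(params$constants)) {
      stop("Unknown parameter target: ", target, call. = FALSE)
    }
    return(list(kind = "constant", name = parts[2]))
  }
  tabs <- c("beta_chol", "beta_sbp", "rr_smoking", "rr_inactivity")
  if (length(parts) != 3 || !parts[1] %in% tabs) {
    stop("Unknown parameter target: ", target, call. = FALSE)
  }
  tab <- params[[parts[1]]]
  row <- which(tab$sex == parts[2] & tab$age_band == parts[3])
  if (length(row) != 1) {
    stop("Unknown parameter target: ", target, " (no such stratum)",
         call. = FALSE)
  }
  col <- if (startsWith(parts[1], "beta")) "beta" else "rr"
  list(kind = "table", table = parts[1], row = row, col = col)
}

set_param <- function(params, target, value) {
  loc <- resolve_target(params, target)
  if (loc$kind == "constant") {
    params$constants[[loc$name]] <- value
  } else {
    params[[loc$table]][[loc$col]][loc$row] <- value
  }
  params
}

get_param <- function(params, target) {
  loc <- resolve_target(params, target)
  if (loc$kind == "constant") params$constants[[loc$name]]
  else params[[loc$table]][[loc$col]][loc$row]
}

#' Default sampling distributions for the effect parameters
#'
#' One distribution per stratum-specific effect parameter: normal on the
#' coefficient scale for the beta coefficients (sd = reported standard
#' error) and lognormal on the excess relative risk for the RRs (so draws
#' stay above 1; log-scale sd recovered from the 95% CI). Translation
#' constants are not sampled by default.
#'
#' @param params An `effect_parameters` bundle.
#' @return A list of [param_dist()] objects.
#' @export
default_distributions <- function(params) {
  out <- list()
  for (tab in c("beta_chol", "beta_sbp")) {
    t <- params[[tab]]
    for (i in seq_len(nrow(t))) {
      out[[length(out) + 1]] <- param_dist(
        paste(tab, t$sex[i], t$age_band[i], sep = "/"),
        "normal", location = t$beta[i], scale = t$se[i])
    }
  }
  for (tab in c("rr_smoking", "rr_inactivity")) {
    t <- params[[tab]]
    for (i in seq_len(nrow(t))) {
      sdlog <- (log(t$ci_high[i] - 1) - log(t$rr[i] - 1)) / 1.96
      out[[length(out) + 1]] <- param_dist(
        paste(tab, t$sex[i], t$age_band[i], sep = "/"),
        "lognormal", location = t$rr[i], scale = sdlog, shift = 1)
    }
  }
  out
}

#' Monte Carlo uncertainty intervals
#'
#' Repeatedly redraws the targeted parameters from their distributions,
#' re-evaluates the model, and reports empirical 2.5th / 97.5th percentile
#' uncertainty intervals around the noise-free point estimate. Draws are
#' independent across parameters and iterations.
#'
#' @param model A function taking an `effect_parameters` bundle and
#'   returning a named numeric vector of output quantities.
#' @param params The central `effect_parameters`.
#' @param dists List of [param_dist()] objects (every target must resolve
#'   inside `params`).
#' @param n_draws Number of Monte Carlo iterations (>= 1); 10,000 for
#'   reported intervals.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param draws_file Optional path: stream the per-draw outputs to CSV for
#'   audit.
#' @return A tibble of class `uncertainty_intervals`: `quantity`, `point`,
#'   `low`, `high`, `n_draws`, `seed`.
#' @export
monte_carlo <- function(model, params, dists, n_draws = 10000, seed,
                        draws_file = NULL) {
  stopifnot(n_draws >= 1)
  for (d in dists) resolve_target(params, d$target)  # fail fast
  point <- model(params)
  draws <- with_local_seed(seed, {
    out <- matrix(NA_real_, nrow = n_draws, ncol = length(point),
                  dimnames = list(NULL, names(point)))
    for (i in seq_len(n_draws)) {
      p_i <- params
      for (d in dists) p_i <- set_param(p_i, d$target, draw_param(d))
      out[i, ] <- model(p_i)
    }
    out
  })
  if (!is.null(draws_file)) {
    readr::write_csv(tibble::as_tibble(draws), draws_file)
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- tibble::tibble(
    quantity = names(point), point = unname(point),
    low = unname(qs[1, ]), high = unname(qs[2, ]),
    n_draws = n_draws, seed = seed
  )
  class(out) <- c("uncertainty_intervals", class(out))
  out
}

#' Monte Carlo intervals for a scenario's DPP outputs
#'
#' Convenience wrapper: propagates the default parameter distributions
#' through [run_scenario()]'s accounting for one scenario, reporting the
#' total DPP, per-factor-by-sex DPPs, and the net 2025 deaths. The trend
#' fits and stratum alignment are computed once, so each draw only redoes
#' the scenario arithmetic.
#'
#' @param scenario A [chd_scenario()].
#' @param inputs A `chd_inputs` bundle.
#' @param fits Optional precomputed trend fits.
#' @param params Central effect parameters (default `inputs$params`).
#' @param dists Parameter distributions (default
#'   [default_distributions()]).
#' @inheritParams monte_carlo
#' @return An `uncertainty_intervals` tibble.
#' @export
mc_scenario <- function(scenario, inputs, fits = NULL,
                        params = inputs$params,
                        dists = default_distributions(params),
                        n_draws = 10000, seed, form = "linear") {
  ctx <- scenario_context(inputs, fits)
  model <- function(p) {
    core <- scenario_dpp_core(scenario, ctx, align_params(p), form = form)
    comp <- vapply(c("cholesterol", "sbp", "smoking", "inactivity"),
                   function(f) {
                     c(male = sum(core[[f]][ctx$sex == "male"]),
                       female = sum(core[[f]][ctx$sex == "female"]))
                   }, numeric(2))
    total <- sum(comp)
    c(total_dpp = total,
      stats::setNames(as.vector(comp),
                      paste(rep(colnames(comp), each = 2),
                            rownames(comp), sep = "_")),
      net_2025 = ctx$baseline_total_2025 - total)
  }
  monte_carlo(model, params, dists, n_draws = n_draws, seed = seed)
}

#' Sensitivity of diet-attributable deaths to the saturated-fat change
#'
#' Evaluates diet-only scenarios (salt, smoking and inactivity held at no
#' change) over a grid of saturated-fat intake changes relative to the
#' sex-specific baseline intakes, reporting the cholesterol-route DPP by
#' stratum and in total for each change. Under the linear regression form
#' the totals scale exactly with the change.
#'
#' @param inputs A `chd_inputs` bundle.
#' @param deltas Saturated-fat changes, E% (signed), e.g.
#'   `c(-10, -5, 0, 5, 10)`.
#' @param baseline_sfa Sex-specific baseline intakes, E%.
#' @param fits Optional precomputed trend fits.
#' @param params Effect parameters (default `inputs$params`).
#' @param form Regression form.
#' @param mix Fat [replacement_mix()].
#' @return A list: `by_stratum` tibble (`delta_sfa`, `sex`, `age_band`,
#'   `dpp_raw`, `dpp_rounded`) and `totals` (`delta_sfa`, `dpp_raw`,
#'   `dpp_rounded`).
#' @export
sfa_sensitivity_sweep <- function(inputs, deltas = c(-10, -5, 0, 5, 10),
                                  baseline_sfa = c(male = 15.9, female = 14.4),
                                  fits = NULL, params = inputs$params,
                                  form = "linear", mix = replacement_mix()) {
  stopifnot(all(is.finite(deltas)))
  ctx <- scenario_context(inputs, fits)
  pv <- align_params(params)
  by_stratum <- dplyr::bind_rows(lapply(deltas, function(d) {
    if (any(baseline_sfa + d < 10) || any(baseline_sfa + d > 20)) {
      warning("Saturated-fat intake outside 10-20 E% at delta ", d,
              " E%: the linear cholesterol translation is extrapolating",
              call. = FALSE)
    }
    # the sweep applies a common signed delta to both sexes
    delta_chol <- sfa_delta_to_cholesterol_delta(d, mix = mix, params = params)
    dpp <- dpp_regression(ctx$deaths_2010, delta_chol, pv$beta_chol,
                          form = form)
    out <- chd_strata()
    out$delta_sfa <- d
    out$dpp_raw <- dpp
    out$dpp_rounded <- round_to_5(dpp)
    out[, c("delta_sfa", "sex", "age_band", "dpp_raw", "dpp_rounded")]
  }))
  totals <- dplyr::summarise(dplyr::group_by(by_stratum, .data$delta_sfa),
                             dpp_raw = sum(.data$dpp_raw), .groups = "drop")
  totals$dpp_rounded <- round_to_5(totals$dpp_raw)
  list(by_stratum = by_stratum, totals = totals)
}
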