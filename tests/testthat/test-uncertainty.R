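params <- default_effect_parameters()

test_that("parameter paths resolve into the bundle, unknown targets error", {
  expect_equal(chdimpact:::get_param(params, "constants/hyp_prev"), 0.37)
  p2 <- chdimpact:::set_param(params, "beta_chol/male/45-54", 0.5)
  expect_equal(chdimpact:::get_param(p2, "beta_chol/male/45-54"), 0.5)
  expect_error(chdimpact:::resolve_target(params, "beta_chol/male/85-94"),
               "Unknown parameter target")
  expect_error(chdimpact:::resolve_target(params, "constants/nope"),
               "Unknown parameter target")
  expect_error(
    monte_carlo(function(p) c(x = 1), params,
                list(param_dist("gamma_chol/male/45-54", "normal", 1, 0.1)),
                n_draws = 2, seed = 1),
    "Unknown parameter target")
})

test_that("distribution families draw on their documented scales", {
  expect_error(param_dist("constants/hyp_prev", "point", 0.37, scale = 0.1),
               "zero scale")
  expect_error(param_dist("x", "normal", 0, scale = -1), ">= 0")
  d <- param_dist("constants/hyp_prev", "point", 0.37)
  expect_equal(chdimpact:::draw_param(d, 5), rep(0.37, 5))
  # shifted lognormal keeps draws above the shift
  rr <- param_dist("rr_smoking/male/25-34", "lognormal", 1.2, 0.5, shift = 1)
  draws <- chdimpact:::with_local_seed(1, chdimpact:::draw_param(rr, 1000))
  expect_true(all(draws > 1))
  expect_equal(median(draws), 1.2, tolerance = 0.05)
})

test_that("point distributions collapse the interval onto the estimate", {
  central <- chdimpact:::get_param(params, "beta_chol/male/45-54")
  dists <- list(param_dist("beta_chol/male/45-54", "point", central),
                param_dist("constants/hyp_prev", "point", 0.37))
  model <- function(p) c(y = chdimpact:::get_param(p, "beta_chol/male/45-54") * 10)
  ui <- monte_carlo(model, params, dists, n_draws = 50, seed = 3)
  expect_equal(ui$low, ui$point)
  expect_equal(ui$high, ui$point)
})

test_that("identical seeds give bitwise-identical intervals; different seeds differ", {
  dists <- default_distributions(params)
  model <- function(p) c(b = chdimpact:::get_param(p, "beta_chol/male/45-54"))
  a <- monte_carlo(model, params, dists, n_draws = 200, seed = 9)
  b <- monte_carlo(model, params, dists, n_draws = 200, seed = 9)
  expect_identical(a, b)
  c <- monte_carlo(model, params, dists, n_draws = 200, seed = 10)
  expect_false(identical(a$low, c$low))
})

test_that("interval width shrinks as the parameter spread shrinks", {
  widths <- vapply(c(0.2, 0.05, 0.01), function(s) {
    ui <- monte_carlo(function(p) c(y = chdimpact:::get_param(p, "beta_chol/male/45-54")),
                      params,
                      list(param_dist("beta_chol/male/45-54", "normal", 0.2, s)),
                      n_draws = 500, seed = 4)
    ui$high - ui$low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("empirical 95% intervals have nominal predictive coverage", {
  # linear model y = beta * c with beta ~ Normal(mu, sd): an independent
  # realization of the model output should fall inside the empirical
  # 2.5-97.5 percentile interval in ~95% of repeated experiments (reduced
  # draw counts keep this quick)
  mu <- 0.3; sd <- 0.05; cc <- 10
  dists <- list(param_dist("beta_chol/male/45-54", "normal", mu, sd))
  model <- function(p) c(y = cc * chdimpact:::get_param(p, "beta_chol/male/45-54"))
  covered <- vapply(1:400, function(i) {
    ui <- monte_carlo(model, params, dists, n_draws = 250, seed = i)
    fresh <- chdimpact:::with_local_seed(1e6 + i, cc * stats::rnorm(1, mu, sd))
    ui$low <= fresh && fresh <= ui$high
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("scenario-level Monte Carlo brackets the deterministic totals", {
  res <- run_scenario(scenario_low_sfa(), default_inputs, fits = default_fits)
  ui <- mc_scenario(scenario_low_sfa(), default_inputs, fits = default_fits,
                    n_draws = 400, seed = 21)
  tot <- ui[ui$quantity == "total_dpp", ]
  expect_equal(tot$point, res$total_dpp, tolerance = 1e-9)
  expect_lt(tot$low, tot$point)
  expect_gt(tot$high, tot$point)
  # component quantities are reported per factor and sex and sum to the total
  expect_setequal(
    setdiff(ui$quantity, c("total_dpp", "net_2025")),
    as.vector(outer(c("cholesterol", "sbp", "smoking", "inactivity"),
                    c("male", "female"), paste, sep = "_")))
  expect_equal(sum(ui$point[!ui$quantity %in% c("total_dpp", "net_2025")]),
               tot$point, tolerance = 1e-9)
})

test_that("the saturated-fat sweep is linear in the applied change", {
  sw <- suppressWarnings(
    sfa_sensitivity_sweep(default_inputs, deltas = c(-10, -5, 0, 5, 10),
                          fits = default_fits))
  tot <- sw$totals[order(sw$totals$delta_sfa), ]
  expect_equal(tot$dpp_raw[tot$delta_sfa == 0], 0)
  expect_equal(tot$dpp_raw[tot$delta_sfa == -5], -tot$dpp_raw[tot$delta_sfa == 5])
  expect_equal(tot$dpp_raw[tot$delta_sfa == -10],
               2 * tot$dpp_raw[tot$delta_sfa == -5])
  # DPP decreases monotonically as saturated fat rises
  expect_true(all(diff(tot$dpp_raw) < 0))
  # extrapolation beyond the supported intake range warns
  expect_warning(sfa_sensitivity_sweep(default_inputs, deltas = -10,
                                       fits = default_fits),
                 "outside 10-20 E%")
})
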