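test_that("the attributable fraction formula behaves over its whole domain", {
  expect_equal(parf(0, 2), 0)          # no exposure
  expect_equal(parf(0.5, 1), 0)        # null relative risk
  expect_equal(parf(0.5, 3), 0.5)      # (0.5*2)/(1+0.5*2)
  expect_equal(parf(1, 4), 0.75)
  expect_error(parf(-0.1, 2), "\\[0, 1\\]")
  expect_error(parf(1.1, 2), "\\[0, 1\\]")
  expect_error(parf(0.5, 0), "positive")
  expect_warning(out <- parf(0.4, 0.5), "protective")
  expect_lt(out, 0)
})

test_that("regression-route DPP follows the stated closed forms and sign convention", {
  expect_equal(dpp_regression(1000, 0, 0.3), 0)
  expect_equal(dpp_regression(1000, -0.5, 0.3), 150)
  expect_equal(dpp_regression(1000, -0.5, 0.3, form = "loglinear"),
               1000 * (1 - exp(-0.15)))
  # a risk-factor increase costs deaths (negative DPP), symmetrically for
  # the linear form
  expect_equal(dpp_regression(1000, 0.5, 0.3), -150)
  expect_error(dpp_regression(-5, 1, 0.3), ">= 0")
  # loglinear never exceeds the baseline deaths
  expect_lt(dpp_regression(1000, -50, 0.3, form = "loglinear"), 1000)
})

test_that("PARF-route DPP is the expected-deaths-weighted PARF difference", {
  expect_equal(dpp_parf(5975, 0.2, 0.2), 0)
  expect_equal(dpp_parf(1000, 0.25, 0.15), 100)
  expect_equal(dpp_parf(1000, 0.15, 0.25), -100)  # antisymmetry
  for (i in 1:20) {
    a <- (i %% 7) / 10; b <- (i %% 5) / 10
    expect_equal(dpp_parf(500, a, b), -dpp_parf(500, b, a))
  }
  expect_error(dpp_parf(100, 1.2, 0.5), "\\(-1, 1\\)")
})

test_that("reported counts round to the nearest 5 with ties away from zero", {
  expect_equal(round_to_5(378), 380)
  expect_equal(round_to_5(812.4), 810)
  expect_equal(round_to_5(2.5), 5)
  expect_equal(round_to_5(-2.5), -5)
  expect_equal(round_to_5(0), 0)
  x <- c(-13.7, 1.2, 7.49, 7.5, 123.4)
  expect_true(all(round_to_5(x) %% 5 == 0))
  expect_true(all(abs(round_to_5(x) - x) <= 2.5))
})

test_that("a null scenario changes nothing", {
  res <- run_scenario(scenario_null(), default_inputs, fits = default_fits)
  expect_equal(res$results$dpp_raw, rep(0, 48))
  expect_equal(res$total_dpp, 0)
  expect_equal(res$net_2025, res$baseline_2025)
})

test_that("scenario accounting is additive: totals equal sums of parts before rounding", {
  res <- run_scenario(scenario_low_sfa(), default_inputs, fits = default_fits)
  expect_identical(res$total_dpp, sum(res$results$dpp_raw))
  expect_equal(sum(res$by_factor$dpp_raw), res$total_dpp, tolerance = 1e-12)
  expect_equal(sum(res$by_sex$dpp_raw), res$total_dpp, tolerance = 1e-12)
  expect_equal(res$net_2025, res$baseline_2025 - res$total_dpp)
  # rounded values stay within 2.5 of raw values
  expect_true(all(abs(res$results$dpp_rounded - res$results$dpp_raw) <= 2.5))
})

test_that("engine output equals the standalone operations on a hand-worked stratum", {
  # smoking-only scenario, checked by hand for men 55-64
  sc <- chd_scenario("smoking_only", smoking_delta = -0.05)
  res <- run_scenario(sc, default_inputs, fits = default_fits)
  params <- default_inputs$params

  ed <- expected_deaths(default_fits, 2025, default_inputs$population_2025)
  e_str <- ed$by_stratum
  e <- e_str$expected_deaths[e_str$sex == "male" & e_str$age_band == "55-64"]
  rf <- default_inputs$risk_factors_2010
  p <- rf$smoking_prev[rf$sex == "male" & rf$age_band == "55-64"]
  rr <- params$rr_smoking$rr[params$rr_smoking$sex == "male" &
                               params$rr_smoking$age_band == "55-64"]
  hand <- e * (p * (rr - 1) / (1 + p * (rr - 1)) -
                 (p - 0.05) * (rr - 1) / (1 + (p - 0.05) * (rr - 1)))
  got <- res$results$dpp_raw[res$results$sex == "male" &
                               res$results$age_band == "55-64" &
                               res$results$factor == "smoking"]
  expect_equal(got, hand, tolerance = 1e-12)
  # other factors are untouched in a smoking-only scenario
  expect_equal(sum(res$results$dpp_raw[res$results$factor != "smoking"]), 0)

  # salt-only scenario, one stratum, against dpp_regression directly
  sc2 <- chd_scenario("salt_only", salt_delta = -1)
  res2 <- run_scenario(sc2, default_inputs, fits = default_fits)
  d <- default_inputs$deaths_2010
  deaths <- d$deaths[d$sex == "female" & d$age_band == "75-84"]
  beta <- params$beta_sbp$beta[params$beta_sbp$sex == "female" &
                                 params$beta_sbp$age_band == "75-84"]
  expect_equal(
    res2$results$dpp_raw[res2$results$sex == "female" &
                           res2$results$age_band == "75-84" &
                           res2$results$factor == "sbp"],
    dpp_regression(deaths, salt_delta_to_sbp_delta(-1, params), beta))
})

test_that("a strictly larger improvement never prevents fewer deaths", {
  totals <- vapply(c(-0.01, -0.03, -0.05), function(d) {
    run_scenario(chd_scenario("x", smoking_delta = d, inactivity_delta = d),
                 default_inputs, fits = default_fits)$total_dpp
  }, numeric(1))
  expect_true(all(diff(totals) > 0))

  for (form in c("linear", "loglinear")) {
    diet <- vapply(c(14, 12, 10), function(tgt) {
      run_scenario(chd_scenario("d", target_sfa = tgt), default_inputs,
                   fits = default_fits, form = form)$total_dpp
    }, numeric(1))
    expect_true(all(diff(diet) > 0))
  }
})

test_that("scenarios pushing prevalence above one are rejected, naming the stratum", {
  sc <- chd_scenario("bad", smoking_delta = 0.9)
  expect_error(run_scenario(sc, default_inputs, fits = default_fits),
               "smoking prevalence above 1 in stratum male")
  # reductions are floored at zero prevalence rather than going negative
  sc2 <- chd_scenario("deep", smoking_delta = -0.9)
  res <- run_scenario(sc2, default_inputs, fits = default_fits)
  expect_true(all(res$results$dpp_raw[res$results$factor == "smoking"] >= 0))
})

test_that("linear and loglinear forms agree to first order and are both labelled", {
  lin <- run_scenario(scenario_low_sfa(), default_inputs, fits = default_fits,
                      form = "linear")
  log <- run_scenario(scenario_low_sfa(), default_inputs, fits = default_fits,
                      form = "loglinear")
  expect_equal(lin$form, "linear")
  expect_equal(log$form, "loglinear")
  chol_lin <- sum(lin$results$dpp_raw[lin$results$factor == "cholesterol"])
  chol_log <- sum(log$results$dpp_raw[log$results$factor == "cholesterol"])
  expect_lt(chol_log, chol_lin)           # 1 - exp(-x) < x for x > 0
  expect_gt(chol_log, 0.9 * chol_lin)     # but close at these effect sizes
})
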