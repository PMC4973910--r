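test_that("the stratum grid has exactly 12 strata covering ages 25-84", {
  s <- chd_strata()
  expect_equal(nrow(s), 12)
  expect_equal(nrow(dplyr::distinct(s)), 12)
  expect_setequal(levels(s$age_band),
                  c("25-34", "35-44", "45-54", "55-64", "65-74", "75-84"))
  expect_setequal(levels(s$sex), c("male", "female"))
})

test_that("stratum completeness validation names what is missing or duplicated", {
  full <- chd_strata()
  expect_silent(assert_strata_complete <- chdimpact:::assert_strata_complete(full))
  expect_error(chdimpact:::assert_strata_complete(full[-3, ]),
               "missing strata.*male 45-54")
  expect_error(chdimpact:::assert_strata_complete(rbind(full, full[1, ])),
               "duplicated")
  bad <- full
  bad$age_band <- as.character(bad$age_band)
  bad$age_band[1] <- "85-94"
  expect_error(chdimpact:::normalise_strata(bad), "Unknown age band")
})

test_that("sex-level risk factor fixtures reproduce the published survey values", {
  # golden check of every cell, all three survey years
  expected <- list(
    male = list(
      "1986" = c(6.15, 0.313, 135.0, 0.028, 24.8, 0.159),
      "2002" = c(5.51, 0.176, 132.9, 0.042, 26.0, 0.127),
      "2010" = c(5.48, 0.132, 134.3, 0.067, 26.3, 0.173)
    ),
    female = list(
      "1986" = c(6.19, 0.266, 132.7, 0.025, 23.8, 0.156),
      "2002" = c(5.51, 0.195, 129.7, 0.034, 24.8, 0.104),
      "2010" = c(5.53, 0.152, 130.8, 0.051, 24.9, 0.120)
    )
  )
  cols <- c("chol_mean", "smoking_prev", "sbp_mean", "diabetes_prev",
            "bmi_mean", "inactivity_prev")
  for (yr in c(1986, 2002, 2010)) {
    overall <- swedish_risk_factors(yr)$overall
    expect_equal(nrow(overall), 2)
    for (s in c("male", "female")) {
      row <- overall[overall$sex == s, ]
      expect_equal(unname(unlist(row[cols])), expected[[s]][[as.character(yr)]],
                   info = paste(s, yr))
    }
  }
})

test_that("2010 age-stratified fixtures reproduce every published cell", {
  by_stratum <- swedish_risk_factors(2010)$by_stratum
  expect_equal(nrow(by_stratum), 12)
  golden <- list(
    male = list(
      chol_mean = c(4.98, 5.36, 5.48, 5.56, 5.57, 5.48),
      smoking_prev = c(11.8, 10.5, 13.8, 18.1, 15.8, 6.0) / 100,
      sbp_mean = c(125.9, 126.4, 131.7, 139.2, 145.4, 151.3),
      diabetes_prev = c(0.9, 1.8, 4.3, 9.4, 15.2, 18.0) / 100,
      bmi_mean = c(25.5, 26.7, 26.7, 26.6, 26.5, 25.6),
      inactivity_prev = c(11.4, 20.0, 19.7, 18.7, 14.8, 20.9) / 100
    ),
    female = list(
      chol_mean = c(4.66, 4.92, 5.51, 5.51, 5.80, 5.68),
      smoking_prev = c(11.3, 14.3, 24.2, 16.7, 13.3, 6.3) / 100,
      sbp_mean = c(118.3, 119.1, 126.5, 136.9, 144.2, 153.3),
      diabetes_prev = c(0.8, 1.4, 2.9, 5.9, 10.4, 14.1) / 100,
      bmi_mean = c(23.6, 24.5, 25.4, 25.3, 25.8, 25.2),
      inactivity_prev = c(9.0, 12.8, 10.6, 9.9, 12.0, 23.3) / 100
    )
  )
  for (s in names(golden)) {
    sub <- by_stratum[by_stratum$sex == s, ]
    sub <- sub[order(sub$age_band), ]
    for (col in names(golden[[s]])) {
      expect_equal(sub[[col]], golden[[s]][[col]], info = paste(s, col))
    }
    # prevalences are fractions, means within physiological ranges
    expect_true(all(sub$smoking_prev >= 0 & sub$smoking_prev <= 1))
    expect_true(all(sub$chol_mean > 2 & sub$chol_mean < 12))
    expect_true(all(sub$sbp_mean > 80 & sub$sbp_mean < 220))
  }
})

test_that("fixture loader rejects years without survey data, naming the options", {
  expect_error(swedish_risk_factors(1999), "1986, 2002, 2010")
  expect_null(swedish_risk_factors(1986)$by_stratum)
  expect_null(swedish_risk_factors(2002)$by_stratum)
})

test_that("regional weighting is a plain convex combination", {
  expect_equal(weighted_national_mean(5, 5, 0.15, 0.85), 5)
  expect_equal(weighted_national_mean(6, 5, 0.15, 0.85), 5.15)
  expect_equal(weighted_national_mean(7.3, 99, 1, 0), 7.3)
  expect_error(weighted_national_mean(6, 5, 0.2, 0.85), "sum to 1")
  expect_error(weighted_national_mean(6, 5, -0.15, 1.15), "non-negative")
})

test_that("diet profiles enforce non-negativity and the energy budget", {
  d <- diet_profile()
  expect_equal(d$salt, 10)
  expect_true(d$sfa_e + d$mufa_e + d$pufa_e <= 100)
  expect_error(diet_profile(sfa_e = -1), "non-negative")
  expect_error(diet_profile(sfa_e = 60, mufa_e = 30, pufa_e = 20), "100")
})
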