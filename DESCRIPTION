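Package: chdimpact
Title: Scenario Projection of Coronary Heart Disease Mortality from
    Dietary and Behavioural Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cell-based comparative risk assessment model for projecting
    coronary heart disease (CHD) mortality under dietary and behavioural
    risk-factor scenarios, following the risk-factor arm of the IMPACT
    model family. Fits exponential decay trends to age- and sex-stratified
    CHD mortality rates and extrapolates expected baseline deaths;
    translates saturated-fat intake changes into total-cholesterol changes
    (Clarke metaregression equations) and salt intake changes into
    systolic blood pressure changes (hypertension-weighted Cochrane
    effects); converts risk-factor changes into deaths prevented or
    postponed via stratum-specific regression coefficients for continuous
    factors and population attributable risk fraction differences for
    binary factors; and propagates parameter uncertainty by Monte Carlo
    simulation. Includes a synthetic-data generator emulating the Swedish
    registry and survey inputs so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
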