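---
title: "Projecting coronary heart disease mortality under dietary risk-factor scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting coronary heart disease mortality under dietary risk-factor scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdimpact)
```

## The model

`chdimpact` implements the risk-factor arm of a cell-based comparative
risk assessment model for coronary heart disease (CHD) mortality, of the
kind widely used to apportion national mortality trends to changes in
population risk factors. The population is divided into 12 cells — two
sexes crossed with six closed 10-year age bands covering ages 25–84 — and
every computation is carried per cell, then summed.

The analysis answers a counterfactual question: if age-specific CHD
mortality keeps declining at its recent pace, how many deaths are
expected in a projection year (2025), and how many of those would be
prevented or postponed (DPP) under specified changes in diet (saturated
fat, salt), smoking, and physical inactivity between the baseline year
(2010) and the projection year?

### Baseline trend extrapolation

For each cell the observed mortality rate series (1986–2010) is modelled
as exponential decay,

$$r(t) = r_{\mathrm{ref}}\, e^{-\lambda (t - t_{\mathrm{ref}})},$$

fitted by ordinary least squares on $\log r(t)$. OLS-on-logs corresponds
to multiplicative (lognormal) rate error, is exactly solvable, and
recovers $(\lambda, r_{\mathrm{ref}})$ to machine precision on noiseless
input; a deaths-weighted Poisson regression (`method = "poisson"`) is
available for users who prefer count-scale error, and the two agree
closely on well-populated cells. The reference year is the *last*
observed year, so the fitted 2010 value anchors the forward projection.
Expected deaths in 2025 are the projected rate times the official-style
population projection, summed over cells; the *constant-rate
counterfactual* instead freezes each cell at its fitted 2010 rate.

Two deliberate edge-case policies: a cell-year with zero deaths makes the
log-rate undefined, and the fit errors rather than silently correcting —
passing `continuity_correction = TRUE` adds 0.5 deaths in the affected
years only. And although projection is intended forward, the closed form
is valid at any year, so back-projection over the observed years (used to
inspect residuals) is permitted rather than forbidden.

### Translating diet into intermediate risk factors

Two published metaregression results link diet to the continuous risk
factors the model uses:

* **Saturated fat → total cholesterol.** Each 1 E% (percent of dietary
  energy) of saturated fat replaced isocalorically by polyunsaturated fat
  changes total cholesterol by 0.078 mmol/L, or 0.048 mmol/L when
  replaced by monounsaturated fat. With the default 90/10
  polyunsaturated/monounsaturated replacement mix the combined
  coefficient is $0.078 \times 0.90 + 0.048 \times 0.10 = 0.075$ mmol/L
  per E%. (A rounded per-E% figure of "0.3" sometimes quoted alongside
  these coefficients is not consistent with their weighted combination;
  the package uses the computed 0.075, which also reproduces the standard
  scenario deltas, e.g. a 5.9 E% reduction giving 0.44 mmol/L.) The
  relationship is treated as linear within the 10–20 E% intake range, and
  the package warns when a scenario leaves that range.
* **Salt → systolic blood pressure.** A 6 g/day salt reduction lowers SBP
  by 7.2 mm Hg in hypertensives and 3.6 mm Hg in normotensives. With 37%
  population hypertension prevalence, held constant over the projection
  period, the population-average effect is
  $[(7.2)(0.37) + (3.6)(0.63)]/6 = 0.822$ mm Hg per g/day.

```{r translations}
salt_delta_to_sbp_delta(-1)
scenario_cholesterol_delta(c(male = 15.9, female = 14.4), target_sfa = 10)
```

### From risk-factor changes to deaths prevented or postponed

Two routes, chosen by the nature of the factor:

* **Continuous factors** (cholesterol, SBP) use the *regression route*:
  baseline-year deaths $D_{2010}$ times the absolute change $|\Delta|$
  times a cell-specific coefficient $\beta$ giving the relative mortality
  change per unit. The default `"linear"` form is the literal product
  $D \cdot |\Delta| \cdot \beta$; the `"loglinear"` alternative
  $D (1 - e^{-\beta |\Delta|})$ is the classic bounded variant. They
  agree to first order, and results tables record the form used.
* **Binary factors** (smoking, physical inactivity) use the *population
  attributable risk fraction* route:
  $\mathrm{PARF} = p(\mathrm{RR}-1) / [1 + p(\mathrm{RR}-1)]$, and
  $\mathrm{DPP} = E_{2025} \times (\mathrm{PARF}_{2010} -
  \mathrm{PARF}_{2025})$, where $E_{2025}$ is the cell's expected deaths
  under continued decline.

Note the base-year asymmetry — observed 2010 deaths for the regression
route, expected 2025 deaths for the PARF route — which is implemented
literally as the method is conventionally stated. Factors are treated as
additive and independent: no mediation between cholesterol and blood
pressure, no interaction terms. Total DPP is therefore exactly the sum of
its per-cell, per-factor parts; the package asserts this conservation
rather than assuming it.

Conventions that keep the accounting reproducible:

* **Sign.** An improvement always yields positive DPP; a deterioration,
  negative.
* **Rounding.** Reported death counts are rounded to the nearest 5, ties
  away from zero — but only at reporting time. All totals are sums of raw
  values; cell-level rounding followed by summation is *not* additive and
  is never used. Percentages are computed from raw values, then shown to
  one decimal.
* **Prevalence floors.** Scenario prevalence changes are absolute
  percentage-point shifts applied uniformly to every age band. A
  reduction larger than a cell's prevalence floors at zero (a policy
  cannot remove more smokers than exist); an increase pushing any cell
  above 1 is an error naming the offending cell, since it indicates a
  mis-specified scenario rather than a boundary case.

### The packaged scenarios

```{r scenarios, eval = FALSE}
scenario_trend_only()  # salt -1 g/day, smoking -5 pp, inactivity -5 pp
scenario_low_sfa()     # the above + saturated fat down to 10 E%
scenario_high_sfa()    # the above + saturated fat up to 20 E%
```

The sex-specific baseline saturated-fat intakes differ between the
low-fat calibration (15.9 E% men / 14.4 E% women) and the high-fat one
(17.5 / 16.0 E%), reflecting the different survey vintages behind the two
dietary comparisons; both are plain arguments and can be overridden.

## The synthetic data generator

No registry or survey microdata ship with the package. Instead,
`synthetic_sweden()` assembles inputs with the statistical structure the
model assumes:

* per-cell mortality rate series that decay exponentially from 1986
  levels, with death counts either deterministic (expected values,
  rounded) or Poisson-distributed around them;
* population series interpolating between realistic 1986 and 2010 age
  structures, plus a 2025 projection with the expected ageing of the
  population;
* the published 2010 risk-factor survey tables (these are real printed
  population-level values, the only non-synthetic ingredient);
* effect parameters — cell-specific $\beta$ coefficients and relative
  risks — for which the true source tables are not reproducible here.

The packaged default parameter files (`inst/extdata/synthetic_*.csv`,
deliberately labelled synthetic) were **calibrated once**: age/sex shapes
were fixed on epidemiological grounds (coefficient magnitudes decreasing
with age; male rates exceeding female; relative risks above 1 and larger
at younger ages), then per-sex scale factors were solved so that the
deterministic pipeline reproduces the published headline magnitudes —
about 5,975 expected deaths in 2025 (4,010 men, 1,965 women) versus about
11,000 under constant rates, and low-fat-scenario DPP components of about
300/130 (cholesterol), 90/50 (salt), 90/60 (smoking) and 60/30
(inactivity) for men/women. The calibration is part of the shipped study
conditions and is not adjusted thereafter. Because the coefficients are
calibrated stand-ins, *absolute* DPP values are calibration-dependent;
the analytic constants, ratios, conservation properties and statistical
behaviour are what the package promises, and those are what the test
suite pins down. One consequence of linearity worth stating: having
calibrated the cholesterol route to the low-fat components, the high-fat
scenario's cholesterol penalty is fully determined by its (smaller)
cholesterol increment, so its net outcome is more favourable than
published figures that imply an asymmetric cholesterol response.

What the generator does **not** emulate: diagnostic/coding changes over
the observation period, cohort effects or joinpoints in the decline,
migration in the population projection, correlation between risk factors
within individuals, and survey measurement error in the 2010 risk-factor
levels. Passing tests therefore certify the model mechanics and the
statistical contracts, not registry realism.

## Uncertainty propagation

`monte_carlo()` redraws targeted parameters from declared distributions,
re-evaluates the scenario, and reports empirical 2.5th/97.5th percentile
intervals from 10,000 draws (the reported setting; tests use fewer). The
default distribution set samples the effect parameters only — normal on
the coefficient scale for $\beta$s (sd = standard error), lognormal on
the *excess* relative risk for RRs so draws stay above 1 (log-sd
recovered from the 95% CI) — with all draws independent: no correlation
structure is asserted because none is documented for inputs of this kind.
Risk-factor levels themselves are treated as fixed survey values. The
spread parameters are stand-ins in the same sense as the coefficients, so
interval *widths* are illustrative; interval *mechanics* (seeded
reproducibility, degenerate collapse, quantile behaviour, ~95% predictive
coverage) are tested properties.

All randomness flows from explicit integer seeds; generators restore the
caller's RNG state, and the pipeline expands one top-level seed into
fixed per-stage offsets so partial reruns reproduce.

## Numerical and testing choices

Problem sizes used by the test suite were chosen to make the statistical
assertions sharp at interactive runtimes: trend-recovery bias is measured
over 200 Poisson-noised replicates of a 25-year, ~1,000-deaths/year
series (mean $\hat\lambda$ within 0.002 of truth); Monte Carlo quantile
accuracy is checked against closed-form normal quantiles at 10,000 draws
(2% relative tolerance); predictive coverage is estimated over 400
seeded experiments at 250 draws each (95% ± 3 points). The saturated-fat
sensitivity sweep is asserted to be *exactly* linear per cell under the
linear form — a structural identity, not a statistical one.

## Limitations

* Medical treatment uptake, BMI and diabetes are not model terms (the
  latter two enter only implicitly through the fitted mortality trend);
  no competing risks, comorbidity, or life-years-gained accounting.
* A single exponential decay per cell; no joinpoint or segmented trends.
* Trans fats, dietary cholesterol, fibre and carbohydrate substitutions
  are outside the fat-replacement translation.
* The PARF route assumes prompt, full reversibility of the excess risk of
  the binary exposures over the projection horizon.
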