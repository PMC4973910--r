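#!/usr/bin/env Rscript
# Assemble the model inputs: the packaged synthetic Swedish CHD mortality
# series (1986-2010), population projections, and the 2010 risk-factor
# survey tables. Writes the input tables under results/ so later stages
# (and any outside reanalysis) start from plain CSV.
library(chdimpact)

dir.create("results", showWarnings = FALSE)

inputs <- synthetic_sweden()          # deterministic expected-count inputs

write_mortality_csv(inputs$series, "results/mortality_series.csv")
readr::write_csv(synthetic_population(), "results/population.csv")
readr::write_csv(inputs$risk_factors_2010, "results/risk_factors_2010.csv")

d2010 <- inputs$deaths_2010
cat(sprintf("Mortality series: %d strata x %d years (1986-2010)\n",
            length(unique(paste(inputs$series$sex, inputs$series$age_band))),
            length(unique(inputs$series$year))))
cat(sprintf("CHD deaths in 2010: %d (male %d, female %d)\n",
            round(sum(d2010$deaths)),
            round(sum(d2010$deaths[d2010$sex == "male"])),
            round(sum(d2010$deaths[d2010$sex == "female"]))))
cat(sprintf("Mean diet profile: SFA %.1f E%%, salt %.0f g/day\n",
            inputs$diet$sfa_e, inputs$diet$salt))

# a seeded Poisson-noise replicate, to show what sampling variation in the
# registry counts would look like
noisy <- synthetic_sweden(seed = 1)
cat(sprintf("Poisson replicate (seed 1) 2010 deaths: %d\n",
            round(sum(noisy$deaths_2010$deaths))))
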