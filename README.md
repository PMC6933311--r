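# sealflux

Doubly labelled water (DLW) bioenergetics of central-place foraging fur
seals: a tested R implementation of the full analysis chain from raw
isotope, mass, dive, track and milk fatty-acid inputs to at-sea field
metabolic rate (FMR), water influx, foraging success, diet clusters, and
model-averaged covariate effects.

## Who this is for

Ecophysiologists and marine mammal ecologists working with DLW
measurements of animals that alternate foraging trips with shore
attendance (otariids and other central-place foragers). The package
ships the complete 48-measurement foraging-trip table of lactating
northern fur seals (*Callorhinus ursinus*) from the Pribilof Islands as
a built-in dataset, so every downstream statistic is reproducible on a
laptop, and a synthetic-data generator with known ground truth so every
estimator is testable without any field data.

## The model

DLW estimates CO₂ production from the differential washout of two
labels: ¹⁸O leaves the body as water **and** respired CO₂, tritium as
water only. With `N` the body water pool (mol) and `kd`, `ko` the ³H and
¹⁸O turnover rates (day⁻¹) from log-linear decline of
background-corrected concentrations,

    rCO2 (mol/day) = (N / 2.078) (ko − kd) − 0.0062 kd N
    FMR  (W/kg)    = rCO2 · 22.4 L/mol · 23.9 kJ/L · 1000 / 86400 / mass

TBW comes from ¹⁸O dilution (plateau method initially, body-mass scaling
finally), the at-sea FMR component strips shore time at an assumed
onshore rate, water influx is `kd` times the mean pool plus net pool
change, and mass gain is fasting-adjusted for time ashore. Behavioural
covariates come from zero-offset-corrected depth series (dives > 3 m),
speed-filtered ARGOS tracks (3 m s⁻¹), and milk fatty-acid signatures
clustered in centred-log-ratio space (Ward on squared Euclidean
distances, adaptive tree cut, LDA for the discriminating FAs).
Covariate effects on at-sea FMR and foraging success are assessed by
all-subsets AICc model averaging (maximum likelihood, random intercept
per seal, conditional averaging over the 95% confidence set).

## Worked example

```r
library(sealflux)

tab <- load_study_table("table1")
attr(tab, "n_measurements")   # 48
attr(tab, "n_seals")          # 33

summarize_column(tab, "pct_dive")
#>     column     mean       sd min  max  n
#> 1 pct_dive 13.22292 3.840448 5.7 23.9 48

fit <- fit_candidates(tab, "at_sea_fmr",
                      c("season", "trip_duration", "pct_dive",
                        "mean_max_depth", "fa_cluster", "tag_fsa"),
                      random = "seal_id")
round(fit$averaged["(Intercept)", "estimate"], 2)   # 7.35  W/kg
round(effect_as_percent(fit, "seasonfall"), 1)      # 7.3   % increase in fall
round(effect_as_percent(fit, "trip_duration"), 1)   # -2.1  % per trip day
```

The averaged intercept is the at-sea FMR (W kg⁻¹) of a reference
summer trip; the percent effects say that at-sea FMR runs about 7%
higher in fall and drops about 2% for each extra day at sea. The season
and trip-duration CIs exclude zero; diving behaviour, diet cluster and
tag size show no effect.

A full synthetic study with known truth, end to end:

```r
sim <- simulate_study(simulation_config(seed = 1))
est <- estimate_study(sim)                 # DLW chain on simulated records
max(abs(est$r_co2 - est$true_rco2) / est$true_rco2)   # ~1e-15 noise-free
```

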