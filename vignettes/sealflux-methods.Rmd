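---
title: "Methods: DLW bioenergetics, behaviour and diet of a central-place forager"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DLW bioenergetics, behaviour and diet of a central-place forager}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealflux)
```

`sealflux` implements the full analysis chain of a doubly labelled water
(DLW) field study of lactating northern fur seals: isotope kinetics to
at-sea field metabolic rate (FMR) and water influx, time-depth-recorder
(TDR) dive metrics, ARGOS track filtering, compositional clustering of
milk fatty-acid (FA) signatures into diet groups, and all-subsets AICc
model averaging of the covariate effects on FMR and foraging success.
This vignette documents the models, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The DLW model

A seal is dosed with H~2~^18^O and tritiated water; ^18^O leaves the body
as water and as respired CO~2~, while ^3^H leaves only as water, so the
differential washout measures CO~2~ production. The chain is:

**Total body water (TBW).** The plateau (initial) method divides the
moles of excess ^18^O delivered by the excess enrichment of the
equilibration sample and corrects the ^18^O dilution space down to a
water pool with a dilution-space factor (default 1.007, the conventional
value; configurable). The scaling (final) method assumes constant
fractional water content: `TBW_final = TBW_initial * mass_final /
mass_initial`. The method names are standard; since the source analysis
does not spell out its scaling formula, the body-mass-ratio form is our
documented choice.

**Turnover.** Fractional turnover rates come from the log-linear decline
of background-corrected concentrations,
`k = [ln(C0 - Cbg) - ln(Cf - Cbg)] / dt` (day^-1^), giving `kd` from
^3^H and `ko` from ^18^O. A final concentration at or below background is
a classed error — exactly the failure mode that discards long
deployments in the field (45 of 93 measurements in the original study).

**CO~2~ production.** The default is the two-pool form
`rCO2 = (N / 2.078)(ko - kd) - 0.0062 kd N` (mol day^-1^, N in mol),
converted at 22.4 L mol^-1^. The source study cites but does not print
its equation, so the equation is a configuration switch: a
fractionation-corrected single-pool alternative
(`- 0.0246 * 1.05 * N (ko - kd)`) is provided, and the forward simulator
is the arbiter of internal consistency — every estimator inverts its
simulator exactly in the noise-free limit, whichever equation is
configured.

**FMR.** Energy at 23.9 kJ per litre of CO~2~, expressed per kg of the
mean of initial and final mass (a symmetric choice; the reference mass is
not stated in the source). The at-sea component strips the onshore
fraction: `FMR_sea = (FMR_total * interval - MR_shore * t_shore) /
t_sea`. The onshore rate is a required configuration parameter with *no
default in code*, because published analyses take it from the captive /
onshore literature rather than measuring it; values near 3–4 W kg^-1^
are typical for lactating otariids. `FMR_sea` decreases strictly as the
assumed onshore rate grows; a non-positive result warns that the
assumption is too high.

**Water influx.** With the pool changing linearly over the interval,
efflux is `kd` times the mean pool and influx is efflux plus the net
pool change, reported in ml kg^-1^ day^-1^. A log-mean ("exponential
pool") variant would differ only in the third decimal at the pool
changes seen here.

**Fasting-adjusted mass gain.** Seals fast ashore, so mass gain at sea is
raw mass change plus a season-specific fasting rate times the shore time
inside the interval. The rates ship as configuration (illustrative
defaults 0.5 / 0.7 kg day^-1^ for summer / fall, the order of magnitude
reported for fasting lactating fur seals); analyses of real data should
set them from the literature for their species.

## Dive metrics

TDRs sample depth at 5 or 10 s with 1 m resolution. Zero-offset
correction estimates a slowly varying surface baseline as the 10th
percentile of depth in a centred 2 h rolling window, median-smoothed and
linearly interpolated between anchors an eighth of a window apart (the
baseline is constrained to vary slowly, so dense evaluation adds nothing
but cost), then subtracts it, flooring corrected depths at -1 m. The
original analysis used proprietary 1990s software whose algorithm is
undocumented; this replacement is fixed and documented instead of
equivalent. A dive is a maximal run of samples strictly deeper than 3 m
(boundary samples are surface, matching the ">3 m" definition); trip
summaries report the dive count, mean of per-dive maximum depths, percent
of trip time diving, and — when night windows are supplied, since no
solar ephemeris is computed — the percentage of dives whose midpoint
falls at night.

## Tracks

ARGOS classes B and Z are dropped; remaining fixes pass a recursive
transit-rate filter (default 3 m s^-1^) that repeatedly removes the
member of the fastest offending adjacent pair that is also moving faster
towards its other neighbour, keeping endpoints while interior
alternatives exist. With two fixes nothing can be removed, so that
degenerate pair may still exceed the limit — documented rather than
hidden. Distances are haversine on a 6371 km sphere, ample at these
speeds. Hourly positions come from great-circle interpolation by
default; `ctcrw_lite`, a fixed-parameter correlated-velocity Kalman
smoother on a local planar projection, is provided for noisy dense
tracks but is deliberately not a substitute for full continuous-time
movement models. Habitat classification is nearest-node lookup into
user-supplied bathymetry and mixed-layer-depth grids (shelf when
shallower than a configurable isobath, default 200 m — the source maps
50/100/200 m contours without naming its classification contour);
positions outside a grid are `unknown`, never guessed.

## Fatty-acid diet clusters

Profiles keep the dietary FAs whose study-wide mean is at least 0.5%,
are re-closed to 100%, zero-replaced multiplicatively (0.65 times the
row's smallest nonzero value) and mapped by the centred log ratio. Ward
clustering runs on squared Euclidean distances (the `ward.D`-on-squared
dialect, heights in squared-distance units, selectable because the
squared distance is named explicitly in the source; `ward.D2` is the
toggle).

The number of clusters comes from an adaptive tree cut. No fixed cut
height exists that handles clusters of unequal tightness, so branches
are tested for a "join-jump": a subtree of at least `min_cluster_size`
members (default 20; the source does not state its minimum) whose own
merge height is exceeded by its parent's joining height by more than
`gap_ratio`. The minimal such nodes become cluster cores — nested
separation resolves at its finest stable level, and a chance core inside
a larger cluster cannot fragment it because surrounding points re-adopt
its label through a bottom-up tree walk. The threshold `gap_ratio = 4`
was calibrated by simulation: across Ward trees of homogeneous Gaussian
clouds (n = 30–300, p = 5–19) the largest parent/child height ratio at
eligible sizes stayed near 3, while even weakly separated (2 SD) clusters
jumped above 5. All decisions are deterministic; identical profiles
(all heights zero) give a single cluster.

Cluster-separating FAs are ranked by multiclass Fisher LDA on the clr
coordinates. The clr constraint makes the within-class scatter exactly
rank-deficient, so the generalized eigenproblem uses a pseudo-inverse on
the data subspace; a truly degenerate scatter (identical members within
classes) is ridge-regularized with a warning. Rankings use standardized
loadings (raw loading times pooled within-class SD) on the leading
discriminant.

## Model averaging

Candidate sets are **all main-effect subsets** (no interactions — none
are reported in the source) of the stated covariates, fitted by maximum
likelihood: REML likelihoods are not comparable across fixed-effect
structures, so ML is required for AICc. At-sea FMR models carry a random
intercept per seal; following the original account, the random effect is
dropped for a model *set* only when every candidate estimates its
variance at exactly zero (as happens for the mass-gain responses), not
per-candidate — per-candidate refitting changes parameter counts
mid-set and demonstrably distorts the averaged intercept. `AICc = -2l +
2k + 2k(k+1)/(n-k-1)` with `k` counting fixed effects plus variance
components. Akaike weights are normalized over all candidates; the 95%
confidence set is the minimal weight-sorted prefix reaching 0.95
(including the crossing model). Coefficients are conditionally
("naturally") averaged — over confidence-set models containing them,
with renormalized weights — because the source reports *conditional*
coefficients; unconditional SEs follow Burnham & Anderson and CIs are
normal-based (no df correction is reported). Percent effects are the
averaged coefficient over the averaged intercept.

On the packaged table, the at-sea FMR set uses season, trip duration,
percent time diving, mean maximum depth, FA cluster and tag frontal
surface area; the foraging-success sets add at-sea FMR but must omit
initial mass, which the printed table does not contain — refits of the
printed data therefore track, but cannot exactly equal, the published
coefficients, and reports flag this.

## The synthetic generator

`simulate_study()` draws 33 seals (a realistic fraction measured in both
seasons), trip durations of 6.4 ± 1.7 d, masses within 26–47.6 kg, an
at-sea FMR linear model with intercept 7.36 W kg^-1^, +7.2% fall and
-1.9% per-trip-day effects, cluster-specific water influx means
(187.7/158.1/144.3 ml kg^-1^ day^-1^), and a mass-gain model with
+0.6 kg day^-1^ and +1.8 kg fall effects — the study conditions. Isotope
records are *forward-computed from the same equations the estimators
invert* (generator/estimator adjointness), with multiplicative lognormal
assay noise (default CV 1%) and an exclusion flag when the final ^18^O
excess falls below a detection limit, emulating measurements lost to
background. Depth series are trapezoidal dive bouts placed
preferentially (p = 0.818) in a 20:00–06:00 night window at 1 m / 5–10 s
resolution; tracks are out-and-back correlated random walks with
class-dependent ARGOS error; FA profiles are Dirichlet draws around four
synthetic centroids (squid-like, age-0 pollock-like, adult pollock-like,
mixed). The Dirichlet concentration (default 2000) was set so the
log-scale within-cluster variability of *minor* FAs (~25–30%) matches
what milk-FA datasets show: a Dirichlet ties trace-component variance to
the total concentration, and a value calibrated only to major-FA scatter
would make trace FAs unrealistically noisy in exactly the clr
coordinates the clustering uses.

What the generator does **not** emulate: real oceanography or prey
fields, isotope fractionation corrections beyond the equation constants,
tag failures, behavioural states, or the sampling correlations of real
ARGOS duty cycles. Passing recovery tests therefore demonstrates the
*estimators invert the assumed measurement model*, not that field data
meet those assumptions.

## Problem sizes and numerical choices

The test-suite simulations use 100-seal recovery runs, 500-replicate
noise and recovery experiments on plain linear candidate sets at n = 48,
291-trip FA recoveries, and one full 33-seal end-to-end run with depth
series and tracks — sizes chosen so each suite completes in seconds
while keeping Monte-Carlo error well inside the asserted tolerances.
Ties in Ward merges follow the deterministic agglomeration order; the
speed filter breaks ties towards removing the later fix; timestamps are
UTC and durations decimal days throughout.

## Interfaces

The package's functions are the interface; `reproduce_results()` is the
one-call entry point that recomputes the study's headline numbers from
the packaged table (or from a synthetic study), and
`scripts/acceptance.R` wraps it for scripted runs. Known limitations:
equivalence with the original proprietary dive software cannot be
tested; the published foraging-success intercepts include an
initial-mass covariate the printed table lacks; and two-fix tracks
cannot be speed-filtered.
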