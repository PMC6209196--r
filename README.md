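# wolfsnow

Do short-term snowfall events change how much — and how fast — grey
wolves (*Canis lupus*) travel in winter? `wolfsnow` is an R package for
answering that question from two plain inputs: GPS collar fixes and
daily snow-depth readings from remote cameras aimed at marked poles. It
is aimed at movement ecologists working with winter telemetry who want a
tested, reproducible pipeline rather than a one-off script.

The pipeline:

1. **Telemetry** — clean and thin fixes to a 30-min grid, compute step
   speeds (m/min, Euclidean on projected coordinates), assign each fix a
   *camera-day* (fixes after local noon match the next day's noon
   photo), and label steps day/night from NOAA sunrise/sunset at the
   wolf's daily centroid.
2. **Segmentation** — fit a two-component Gaussian mixture to pooled
   log10 step speeds by EM and classify steps as *rest* or *travel* at
   the exact density intersection,
   `w1 N(x; mu1, sd1) = w2 N(x; mu2, sd2)`, solved as a quadratic in x.
   The published threshold for this system, 1.65 m/min, ships as
   `reference_cutoff_mpm`.
3. **Snow** — difference each camera's daily depth series into 24-h
   accumulations and flag *snowfall events* (accumulation ≥ 5 cm);
   join snow values to wolf-days via the nearest active camera.
4. **Windows** — place each wolf-day in one of seven snowfall
   categories (`two_before` … `three_after`, plus randomly sampled
   `control` days at least 3 days before or 4 days after every event).
5. **Inference** — fit the 10-model candidate set
   `metric ~ snowfall_category * time_of_day + snow_depth` (and
   sub-models) as mixed models with lme4: a linear mixed model on log10
   travel speed (by-wolf random intercept + time-of-day slope) and a
   binomial GLMM on travel/rest (by-wolf random intercept). Rank by
   AIC = 2K − 2logL with Akaike weights
   `w_i = exp(-Δ_i/2) / Σ_j exp(-Δ_j/2)`, apply a parsimony rule within
   ΔAIC ≤ 4, and get percentile CIs by parametric bootstrap. Back-
   transform coefficients with `10^β` (speed) or `exp(β)` (odds).

A synthetic-data generator (`sim_config()`, `simulate_dataset()`)
emulates the study conditions — 17 wolves over 60 winter days, 14
cameras with localized 5–16 cm events — so the whole pipeline runs and
is tested without any restricted data.

## Worked example

```r
library(wolfsnow)

run <- run_all(run_config(
  sim  = sim_config(seed = 42),  # synthetic study; or pass input CSVs
  seed = 42
))
print(run)
#> wolfsnow pipeline run
#>   14806 analysis steps, 17 wolves
#>   rest/travel cutoff: 3.695 m/min
#>   best speed model:  log10_speed ~ snowfall_category + time_of_day + snow_depth_cm + (1 + time_of_day | wolf_id) (K = 13)
#>   best travel model: behavior ~ snowfall_category + snow_depth_cm + (1 | wolf_id) (K = 9)

head(run$travel_table[, c("rank", "name", "K", "AIC", "delta_AIC", "akaike_weight")])
#>   rank              name  K      AIC  delta_AIC akaike_weight
#> 1    1     cat_tod_depth 10 18564.25  0.0000000  4.649914e-01
#> 2    2         cat_depth  9 18564.41  0.1559525  4.301107e-01
#> 3    3   cat_x_tod_depth 16 18567.50  3.2508640  9.152269e-02
#> 4    4         tod_depth  4 18572.63  8.3716500  7.072357e-03
#> 5    5        snow_depth  3 18572.86  8.6020327  6.302854e-03
#> 6    6 snowfall_category  8 18616.36 52.1094597  2.249156e-12
```

The 14,806 analysis steps are the subset of ~49,000 steps that fall in
an event window or on a sampled control day. The printed cutoff is the
fitted mixture-density intersection in m/min (the generator's slow and
fast modes sit near 10^-0.3 ≈ 0.5 and 10^1.2 ≈ 16 m/min, so the
crossing lands between them). The tables rank all ten candidates per
movement metric; here the parsimony rule picks the K = 9
category + depth model over the 0.16-AIC-higher K = 10 leader.
`run$summaries` holds the descriptive tables: travel proportion and
mean ± sd travel speed per snowfall category × time of day, and km/day
per category — on synthetic data the generating event-night drop in
travel probability shows up there directly. Snow depth co-varies with
event windows by construction (events *are* depth increases), so
depth-bearing models ranking high on simulated data is expected
confounding, not a defect.

To reuse the published labelling instead of refitting the mixture, pass
`cutoff = reference_cutoff_mpm` to `run_config()`.

## Documentation

- `vignettes/wolfsnow-methods.Rmd` — the model and procedure in detail:
  assumptions, parameter defaults and units, numerical choices, what
  the synthetic generator does and does not emulate, limitations.
- Function reference via roxygen2 (`?run_all`, `?fit_mixture`,
  `?assign_snowfall_categories`, …).
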