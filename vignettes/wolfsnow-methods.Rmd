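---
title: "Methods: from winter telemetry and camera snow series to snowfall effects on wolf movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from winter telemetry and camera snow series to snowfall effects on wolf movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`wolfsnow` implements a complete analysis chain for a question in winter
movement ecology: do short-term snowfall events change how much, and how
fast, grey wolves travel? The chain starts from two plain inputs — GPS
collar fixes and daily snow-depth readings from remote cameras — and ends
in AIC-compared mixed-effects models of travel speed and travel
probability. A synthetic-data generator with the same statistical
structure stands in for the original collar and camera data, which are
not redistributable, so every stage is testable end to end.

## 1. Telemetry preparation

**Thinning.** Collars record fixes every 10 or 30 min. To compare
individuals on a common footing, fixes are thinned to a 30-min grid
anchored at :00/:30 of the hour: each fix is assigned to its nearest grid
time and at most one fix (the nearest; ties keep the earlier fix) is
retained per slot. A fix exactly midway between two grid times goes to
the later slot; the convention is arbitrary but fixed, and data already
on the grid pass through unchanged. Nearest-to-grid thinning was chosen
over subsampling every third fix because it is idempotent and tolerant of
irregular fix times.

**Steps.** A *step* joins two consecutive fixes of one wolf. Its speed is
the Euclidean distance on projected coordinates divided by the elapsed
minutes (m/min). Steps whose interval falls outside an acceptance band —
default 19.75–40.92 min, the observed range of nominal-30-min data —
are dropped rather than interpolated: a gap spanned by a long step would
understate speed and misplace the animal in time.

**Camera-days.** Snow cameras photograph once daily at noon, so a photo
integrates snowfall over the preceding 24 h. A fix taken after local noon
can only be matched to the *next* day's photo; its "camera-day" is
therefore the next calendar date. A fix at exactly 12:00:00 keeps its
date (the noon photo is contemporaneous with it). Local time is UTC plus
a fixed configurable offset (default −7 h, Mountain Standard Time; the
study window, January–March, has no daylight saving).

**Day and night.** Each step is labelled day or night by comparing its
end time against sunrise and sunset computed with the NOAA low-precision
solar equations (official zenith 90.833°, i.e. refraction-corrected), at
the wolf's *daily centroid* — the mean of its projected coordinates that
camera-day — so a single sunrise/sunset pair applies to the whole
wolf-day. Latitudes beyond ±66.5° are rejected explicitly: the algorithm
and the day/night dichotomy both break down under polar day/night.

## 2. Rest/travel segmentation

Pooled log10 step speeds are strongly bimodal: a slow mode produced by
GPS jitter around a resting or feeding animal, and a fast directed-travel
mode. The package fits a two-component Gaussian mixture by EM with one
deterministic initialization (means at the 25th/75th percentiles, equal
weights, pooled SD), converging when the log-likelihood improves by less
than 1e-8. The classification cutoff is the *density intersection*
between the component means, solved exactly: equating the two weighted
normal log-densities gives a quadratic in x (linear when the SDs are
equal), and the root strictly between the means is the threshold. Steps
at or above the cutoff (in m/min) are "travel", below it "rest".

Numerical choices worth noting:

- Zero-length steps have undefined log speed; speeds are floored at
  0.01 m/min (≈ GPS jitter over 30 min) before the log transform.
- With extreme weight imbalance the densities may not cross between the
  means; this is an error with a suggested quantile fallback, not a
  silent extrapolation.
- The published cutoff for this system, 1.65 m/min, ships as the
  constant `reference_cutoff_mpm` so a user can reproduce the original
  labelling without refitting; `cutoff = "auto"` re-derives it from data.
- The mixture is fitted on speeds pooled across individuals, matching
  how the original threshold was derived.

## 3. Snow series and snowfall events

Daily accumulation at a camera is the first difference of depth over
exactly 24 h; the first day of a series, and any day after a gap longer
than one day, has missing accumulation (a multi-day gap is never spread
across days). A *snowfall event* is a day with accumulation ≥ 5 cm
(threshold inclusive and configurable). Negative accumulation — settling
and melt — is retained as-is and can never trigger an event.

Each wolf-day is matched to exactly one camera: the one nearest the
daily centroid among cameras already deployed on that date, ties going
to the smallest camera id. Joining via daily centroids guarantees one
snow depth and one accumulation value per wolf-day; days whose nearest
camera lacks a reading keep missing snow values rather than borrowing a
neighbour's. Camera-to-centroid distances are reported (km) as a data
quality summary.

## 4. Snowfall categories and controls

Wolf-days are positioned relative to the events that wolf experienced in
seven categories: `two_before`, `one_before`, `day_of_snowfall`,
`one_after`, `two_after`, `three_after`, and `control`. The six
date-based categories form a [−2, +3]-day window around each event — the
longest window that avoids overlap between typical consecutive events.
Where windows of two events do overlap, a day resolves to the nearest
event, ties to the earlier one, and an event date is always
`day_of_snowfall`; the original analysis never needed an explicit
overlap rule, so this one is the package's own, chosen to be
deterministic and order-free.

Controls are drawn per wolf: up to three dates (configurable) sampled
uniformly without replacement from days at least 3 days before or 4 days
after *every* event of that wolf, under a caller-supplied seed. Three per
wolf roughly balances the control sample against the event-window
categories. Days in no category and not sampled as controls are dropped
from the analysis dataset; rows with a category but no snow reading are
kept (models containing snow depth use complete cases).

## 5. Candidate models and selection

Both movement metrics are modelled with the same 10-model candidate set
built from `snowfall_category`, `time_of_day` and `snow_depth`, up to
the global model `snowfall_category * time_of_day + snow_depth`
(interactions always carry their main effects):

- **Travel speed** — linear mixed model on log10 speed of travel steps
  only, with a by-wolf random intercept and random `time_of_day` slope.
  Fits use maximum likelihood, not REML, because AIC comparisons span
  different fixed-effect structures.
- **Travel probability** — binomial GLMM (travel = 1, rest = 0) with a
  by-wolf random intercept, Laplace approximation (bobyqa optimizer).

Reference levels are `day_of_snowfall` and `day`, so every reported
contrast is "relative to the daytime of an event day". The parameter
count K is the number of fixed coefficients plus variance–covariance
parameters: +4 for the LMM (two variances, one correlation, residual),
+1 for the GLMM — a convention that reproduces all published K values
for this design.

Selection uses AIC = 2K − 2logL, Akaike weights
w_i = exp(−Δ_i/2)/Σ_j exp(−Δ_j/2) and evidence ratios. Because nested
models within a few AIC units of the top model are not genuinely
supported when their extra parameters leave the likelihood essentially
unchanged, `select_best()` applies a parsimony rule: among models with
ΔAIC ≤ 4 (configurable), take the one with smallest K, breaking ties by
AIC.

Two numerical details. Models containing snow depth are fitted with
depth centred at its sample mean: an almost-constant depth column
(~40 ± 10 cm) is nearly collinear with the intercept and triggers
spurious convergence failures; centring removes the collinearity while
leaving the slope (per cm), likelihood, K and AIC unchanged. And when
lme4's gradient check still warns at an optimum, the model is restarted
once from that optimum with a second optimizer; the restart replaces the
fit only if it is warning-free at the same deviance. Fits that remain
non-converged are excluded from the selection table with a warning.

## 6. Uncertainty

Confidence intervals for the selected models come from a parametric
bootstrap: responses are simulated from the fitted model (fresh random
effects, and residual noise for the LMM), the model is refitted with
`lme4::refit()`, and percentile intervals are taken over the
coefficient draws (default 5,000 simulations; percentile rather than
basic/normal intervals, the common default for mildly asymmetric
link-scale estimands). Refit failures are dropped and counted, with a
warning above 10%. Coefficients are back-transformed for reporting:
10^β for the log10-speed model (multiplicative effect on m/min), exp(β)
for the logistic model (odds ratio).

## 7. The synthetic-data generator

The generator emulates the study conditions: 17 wolves tracked over 60
winter days at 30-min fixes (10-min available), and 14 cameras in a
~90 km square at 56.4°N. Its defaults are the conditions the analysis
assumes, not tuning knobs:

- **Snow.** Each camera starts at 30–60 cm depth. Events arrive at 4 per
  camera-winter (Poisson count, distinct days), with accumulation
  uniform on 5–16 cm rounded to the 1-cm reading resolution; about half
  of event dates are drawn from a season-wide shared pool
  (`shared_event_prob = 0.5`), mirroring how roughly half of real events
  were seen by a single individual only. Non-event days drift by small
  settling noise strictly below the 5-cm threshold, so injected events
  and detectable events coincide exactly. The accumulation distribution
  beyond its 5–16 cm range is unreported for the original system;
  uniform is assumed.
- **Movement.** Each wolf walks with a persistent heading (small turning
  noise while travelling, diffuse while resting) re-aimed at its home
  range beyond 12 km. Rest/travel states are drawn independently per
  step from a logistic model with night, snowfall-category and per-wolf
  random-intercept terms; travel log10 speeds follow a linear model with
  night and category effects and per-wolf random intercept and night
  slope. The default coefficients are the published estimates for both
  submodels; days outside any event window take the control
  coefficients. Independent state draws make the ground-truth travel
  fraction equal the inverse-logit of the linear predictor exactly,
  which the tests exploit; real wolf behaviour is serially
  autocorrelated, so passing tests demonstrate estimator correctness,
  not realism of state dynamics.
- **Geometry.** Geographic coordinates derive from projected ones by a
  local tangent-plane at the study origin. Over ~100 km the deviation
  from a conformal projection is far below collar GPS error, and the
  mapping's linearity means centroids commute with projection.
- **Reproducibility.** Snow and track modules consume separate RNG
  streams derived from the master seed (seed+1, seed+2), so regenerating
  cameras never perturbs tracks; identical configs give byte-identical
  fixture files.

What the generator deliberately omits: terrain and linear-feature
selection, pack cohesion (wolves are independent), serial correlation in
behaviour, camera failures, and observation error in depth reading
beyond resolution rounding.

## 8. Problem sizes used by the tests

The test suite favours the smallest sizes at which each property is
sharp: brute-force enumerations run on 16–20-day single-wolf fixtures;
Monte-Carlo event-rate checks use 400 replicate seeds of a 2-camera
winter; mixture recovery uses one ~50,000-step simulation (where 0.05
absolute error on component means is a comfortable 3-sigma margin); and
bootstrap coverage uses 50 replicates of 10-wolf datasets with 200
bootstrap simulations each, with the GLMM replicates fitted at nAGQ = 0
(the fixed-effect difference from Laplace is far below the Monte-Carlo
error of the coverage estimate, and refits are several-fold faster).
End-to-end pipeline checks run 5 wolves over 24 days.

## 9. Known limitations

- The two-state segmentation classifies each step independently; no
  hidden-Markov smoothing, and no third state (e.g. local foraging).
- Day/night is a dichotomy; twilight is not modelled.
- Camera retrieval dates are not modelled: a camera is "active" from its
  deploy date onward.
- Control sampling is per wolf-winter, not per event; a per-event
  variant would weight wolves with many events differently.
- Snow depth enters models untransformed (in cm, centred); no
  standardization or nonlinearity.
- The tangent-plane projection is adequate at ~100 km scales only;
  continental-scale data should be projected properly upstream.
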