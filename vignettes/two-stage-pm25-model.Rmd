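---
title: "A two-stage satellite AOD model for daily PM2.5, with synthetic study worlds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage satellite AOD model for daily PM2.5, with synthetic study worlds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ground monitors measure PM2.5 accurately but sparsely, and in many regions
only in recent years. Satellite aerosol optical depth (AOD) is observed
daily on a fine grid but is a column-integrated, unitless quantity whose
relationship to surface PM2.5 varies from day to day with boundary-layer
meteorology. `pm25sat` implements a calibration pipeline that turns two
partially overlapping AOD retrieval streams into daily gridded PM2.5
estimates, extends them backwards in time under an explicit transfer
assumption, and quantifies what that assumption costs at daily, monthly and
seasonal resolution.

Because no public deposit reproduces the original study's proprietary
monitor records or raw satellite granules, the package is built around a
synthetic-data module that generates a full study world — grid, AOD truth,
retrieval streams, meteorology, land use, fires, monitors — from known
parameters. Every claim the test suite makes is a property of the methods,
checked against that known truth.

## Fusing two retrieval streams

The two streams emulate the Dark Target (DT) and Deep Blue (DB) families of
retrievals: DT performs well over dark, vegetated surfaces and fails over
bright ones; DB covers bright surfaces with its own bias and noise. Fusion
is in three steps:

1. **Crosswalk gap-filling.** Ordinary least squares between the daily
   collocated DT and DB values, in both directions, predicts each stream
   where only the other reports. Days with fewer than 10 collocations fall
   back to the pooled (all-day) regression — a robustness choice for sparse
   days; the threshold is the `min_pairs` argument of `fit_crosswalk()`.
2. **Seasonal error calibration.** The gap-filled streams are matched to
   ground reference stations (same cell, same day) and the variance of the
   differences is computed per season and stream. Matching uses no spatial
   or temporal window beyond the cell-day; a variance floor of `1e-4` AOD²
   prevents infinite weights in the degenerate case; seasons with fewer
   than two matches are flagged and combined with equal weights.
3. **Inverse variance weighting.** Where both streams report,
   `AOD_c = (AOD_DT/Var_DT,m + AOD_DB/Var_DB,m) / (1/Var_DT,m + 1/Var_DB,m)`
   for season *m*; the weights sum to one exactly and the result is a
   convex combination. Where one stream reports, its value is used.

Bias is deliberately *not* removed before weighting: the weights use raw
gap-filled values, so the combined stream inherits a compromise of the two
stream biases. The reference NDVI-based combiner (`operational_combine()`)
is included for coverage comparison only: DT above NDVI 0.3, DB below 0.2,
and in the transition band the mean of both when both carry high quality
assurance, otherwise the higher-QA stream.

## The two-stage calibration model

**Stage 1** is a linear mixed-effects model fitted by REML per region
(province), with all covariates centered on their fitting-set means:

```
PM2.5 ~ AOD + WS + PBLH + PS + RH_PBLH + Precip_Lag1 + Fire_spots
        + (1 + AOD | day) + (0 + WS + PBLH + PS + RH_PBLH | season)
```

The day grouping (calendar month-day) carries a correlated random
intercept and AOD slope — the daily PM2.5/AOD relationship — and the season
grouping carries random slopes for the four meteorological variables. Four
season levels barely identify a 4x4 covariance, so a fallback ladder
handles non-convergence: full covariance, then diagonal (independent season
slopes), then no season effects; each step is recorded on the fit object.
Singular fits are accepted — a variance component estimated at zero is a
legitimate boundary estimate, and the suite verifies it is recovered when
the truth is zero.

Regions with sparse monitoring borrow strength through **buffer zones**:
each region's training set grows by concentric rings of neighbouring cells
(nearest centroid distance first) until it contains at least 3,000 records
and 300 distinct days, or the whole domain. A cell covered by several
buffered models receives the unweighted mean of their predictions, which
keeps the national surface continuous across region boundaries.

**Stage 2** is a national generalized additive model of the stage-1
residuals: a two-dimensional thin-plate smooth of the cell centroid
coordinates plus univariate smooths of forest and urban cover. Smoothing
parameters are selected by REML with an additional shrinkage penalty on
each smooth's null space (`select = TRUE`), so that pure-noise residuals
collapse to a constant instead of inventing structure. Basis dimensions
default to `min(100, n/10)` for the coordinate smooth and 10 for the cover
smooths, reduced automatically (with a message) when the data have fewer
unique values. Above 5,000 rows the fit uses `mgcv::bam(discrete = TRUE)`,
the standard fast path at this size; below, `mgcv::gam(method = "REML")`.
Stage 2 is fitted once nationally — the residual equation carries no region
index — and the full prediction is the sum of the two stages, truncated at
zero and flagged where truncation occurred.

## Historical prediction and its evaluation

Historical years are predicted with the model year's day effects, matched
by calendar month-day (February 29 uses February 28); a month-day never
fitted falls back to fixed effects only and is flagged. This is the
"constant same-day-of-year" assumption, and it is wrong in an instructive
way: daily PM2.5/AOD relationships in other years differ, so daily
accuracy degrades, while monthly and seasonal means — which average over
the day-effect noise — remain informative. The test suite reproduces this
ordering (daily < monthly < seasonal R²) on worlds whose historical day
effects are re-drawn from the same covariance.

Evaluation statistics (`compute_stats()`): R² is the squared Pearson
correlation of predicted versus observed (the regression of predicted on
observed supplies slope and intercept); MPE is the mean error, RMSE the
root mean squared error, and RPE = 100·RMSE / mean(observed). Aggregation
rules follow the source conventions exactly: a monthly mean requires more
than five predicted days (>= 6), a seasonal mean more than ten (>= 11), and
evaluation pairing requires at least 25 ground measurements in a month (and
in every month of a season). A season is only evaluated when all three of
its calendar months qualify — which is why multi-year evaluation windows
should contain complete December–February blocks; a single calendar year
has no complete winter.

## Trend analysis

Monthly means (>= 6 daily predictions) are converted to anomalies by
subtracting each cell's multi-year average for that calendar month, which
removes any pure seasonal cycle exactly. Years contributing fewer than six
anomaly months are dropped whole. Trends are ordinary least squares of the
anomaly on fractional time, centered at the period midpoint for numerical
stability (the slope is unchanged); the 95% CI and p-value use the
classical slope standard error under independent homoscedastic errors — no
autocorrelation correction, a documented limitation shared with the
precedent this follows. Piecewise periods (e.g. before/after 2008) are
user-specified; the package does no changepoint detection. Regional series
are means of member-cell anomalies (not anomalies of a regional mean), an
order-of-operations choice made explicit because the alternative differs
when coverage varies across cells.

## The synthetic world

`simulate_world()` generates the default study conditions: a 40x40 grid of
0.1° cells in four rectangular regions, 365 days, 60 monitor cells (45 in
the two eastern regions, 15 elsewhere, leaving the west data-poor so the
buffer rule matters), 8 reference stations, and meteorology on a 0.5°
coarse grid interpolated by IDW (power 2, 4 nearest nodes). Random fields
are white noise low-pass filtered with a Gaussian kernel — cheap, seedable,
and smooth enough for a realistic variogram; daily fields carry AR(1)
persistence. Land cover is a fine categorical raster (forest/urban/other)
from smoothed scores; cells with forest fraction below 0.2 are "bright".
One lead-in day of meteorology is generated so lagged precipitation is
defined from the first study day.

Generative PM2.5 follows the stage-1 equation with slopes applied to
covariates centered at fixed reference levels (`truth_parameters()$ref`),
plus a deterministic spatial surface in coordinates and land cover, iid
noise, and an optional trend; negative totals are truncated at zero after
all additive terms. Key defaults: mean PM2.5 about 77 µg/m³, AOD slope 60
µg/m³ per unit AOD, day-effect SDs of 12 (intercept) and 15 (AOD slope)
with correlation 0.3, residual SD 12, surface amplitude roughly ±15 µg/m³.
The season-slope covariance defaults to zero: with only four season
levels, a fixed meteorology slope and the mean of its four season draws are
confounded, so no estimator can recover both to the precision the recovery
tests demand; season-slope machinery is exercised instead through
explicitly supplied effect tables. Retrieval defaults (DT bias 0.15, DB
crosswalk slope 0.9 with intercept 0.08, missingness 0.70/0.35 for DT and
0.50/0.75 for DB on bright/vegetated cells) were chosen once so that DT is
the scarcer stream over bright surfaces and the fusion's coverage gain
concentrates there.

What the generator does *not* emulate: retrieval physics (missingness is
statistical, not cloud-driven), monitor measurement error, spatially
correlated residuals beyond the smooth surface, terrain, or population.
Passing tests therefore demonstrate correctness of the estimators under
the stated statistical structure, not performance on real satellite data.

Two deliberate consequences of the design are worth naming. First, model
fitting uses the *fused* AOD while truth PM2.5 is generated from the *true*
AOD, so the fitted AOD slope is attenuated relative to 60 — the classical
errors-in-variables effect any real AOD calibration also carries; the
parameter-recovery tests instead fit the same AOD used in generation,
which isolates estimator correctness from attenuation. Second, in a single
multi-year world day effects are keyed by month-day and therefore repeat
across years — the transfer assumption holds by construction; worlds that
violate it are built by re-drawing day effects via `base_world =`.

## Problem sizes and numerical choices

The test suite and acceptance script run on sizes chosen to make the
statistical checks sharp at desk scale: fusion optimality on the default
40x40x365 world over 20 seeds; stage-1 recovery on a 20x20 single-region
world with 32 monitor cells and 365 days over 20 seeds (about 11,700
fitting rows per replicate); cross-validation contrasts on a 12x12
four-region world with 10 folds; temporal transfer on a 24x24 world with a
15-month historical window (so winters are complete); and the 10-year
trend demonstration on a 20x20 world with a piecewise ±(1.97, 0.46)
µg/m³/year injected trend. Buffer thresholds scale with world size in
tests (the 3,000/300 defaults assume the full-size world).

Other numerical conventions: cell ids are 0-based and row-major with rows
along latitude; dates are ISO-8601; great-circle distances use the
haversine formula on a sphere of radius 6,371 km, while Thiessen pixel
assignment and IDW use planar degrees (adequate at sub-degree scale);
centering constants are computed once from the fitting table and applied
unchanged to every prediction table; ties in nearest-pixel assignment
resolve to the first pixel in input order.

## Known limitations

- Trend inference ignores temporal autocorrelation of monthly anomalies.
- The operational combiner's QA behaviour with equal-but-low flags is not
  specified by its source description; both-equal resolves to the mean.
- Buffer expansion uses centroid distance rings, which on a coarse grid can
  add several cells at exactly the same distance in one step.
- R² is squared Pearson correlation throughout; with a biased predictor it
  can exceed the variance-explained interpretation.
- The season random-effect block is estimable but weakly identified with
  four levels; its fallback ladder trades covariance structure for
  convergence rather than failing.
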