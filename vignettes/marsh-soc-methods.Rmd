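---
title: "Methods: depth-explicit SOC stock mapping with spatial cross-validation and an area of applicability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-explicit SOC stock mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modelling problem

Soil cores from tidal marshes report organic carbon density (OCD, g C cm⁻³)
at the centre depth of sampled layers. Field campaigns are strongly clustered
geographically — in the global compilations, over 85% of unique locations
come from three countries — and deep layers are undersampled (roughly 35% of
samples below 30 cm). The mapping task is to turn these cores plus wall-to-
wall landscape covariates into per-pixel SOC stocks (Mg C ha⁻¹) for the
0–30 cm and 30–100 cm layers, together with an honest statement of where the
model may be trusted and how large its errors are expected to be.

`marshstock` treats this as a 3D (depth-explicit) regression problem:

\[ \mathrm{OCD}(x, y, d) = f\big(d,\; X_1(x,y), \dots, X_n(x,y)\big) + \varepsilon \]

with depth \(d\) an ordinary predictor next to the covariates. Modelling the
density rather than a per-layer stock avoids assumptions about the shape of
the depth profile: the learner sees the empirical profile, which in marsh
soils is often nearly flat because carbon concentration and bulk density
trend in opposite directions with depth. Prediction then evaluates \(f\) at
the standard depths 0, 30 and 100 cm and integrates by the trapezoid rule

\[ \mathrm{stock} = \tfrac{\mathrm{OCD}_{top} + \mathrm{OCD}_{bottom}}{2}
   \cdot \mathrm{thickness\,(cm)} \cdot 100 \quad [\mathrm{Mg\,C\,ha^{-1}}], \]

where the factor 100 converts g C cm⁻² to Mg C ha⁻¹. This factor is applied
explicitly and audited by a unit test with known constants. Negative
predictions are clipped at zero — a density cannot be negative; the clip is a
post-hoc constraint on the learner, not part of the model.

The learner is a random forest (`ranger`) with the pinned production
settings mtry = 3, minimum node size 5, 300 trees and impurity (variance
reduction) importance. `tune_ocd_model()` evaluates the standard
5 × 5 × 5 grid (mtry 1–5, node size {1, 2, 3, 5, 10}, trees
{100, …, 500}) under the same spatial folds; on smooth data the RMSE spread
across the grid is small, which is why the defaults are fixed rather than
re-tuned per run. Ties are broken toward fewer trees, then larger node size
(cheaper, more regularised models). Categorical covariates are one-hot
expanded *inside* the model module, and the expansion map is stored on the
fitted model so that the uncertainty machinery operates in exactly the same
predictor space.

# Spatial cross-validation by distance matching

With clustered training data, randomly assigned CV folds mostly test
within-cluster interpolation and flatter the skill estimate. The package
instead builds *k*-fold nearest-neighbour distance-matched (k-NNDM) folds:
folds over unique locations (depth samples never split across folds — that
would leak whole profiles) chosen so that the ECDF of between-fold
nearest-neighbour great-circle distances matches the ECDF of
prediction-to-training distances, measured by the Wasserstein-1 distance
between the two ECDFs.

The search space is a ladder of complete-linkage hierarchical clusterings of
the locations: the dendrogram is cut into \(q = k, k+1, \dots, n\) clusters;
each cut is merged down to \(k\) folds by assigning clusters, largest first,
to the currently smallest fold; the configuration with the smallest
Wasserstein distance wins, ties going to fewer clusters. This variant is
fully deterministic given the inputs, satisfies the matching objective by
construction of the search, and records the achieved distance as `quality`
so the contract is checkable: on clustered-training/dispersed-prediction
scenes the k-NNDM quality beats random folds in at least 9 of 10 seeds (an
acceptance property), and on a small instance the assignment matches an
exhaustive enumeration oracle.

Geographic distance is the haversine on a sphere of radius 6371 km — a
pinned convention; at the scales that matter for fold matching the
difference from an ellipsoidal distance is irrelevant, and a single
convention keeps the quality numbers comparable across runs.

# Dissimilarity index, AOA and expected error

The dissimilarity index of a prediction point is the minimum distance to a
training point in the model's predictor space — each dimension centred and
scaled by *training* statistics and weighted by normalised impurity
importance — divided by the mean pairwise distance among all training points
(computed once). Zero-variance dimensions get weight zero and are flagged.
For the training points themselves the DI excludes neighbours in the same CV
fold, mirroring how the CV residuals were produced; prediction-pixel DI uses
all training points (published descriptions of the routine leave this unstated; using the
full reference is the conservative choice, giving the smallest DI and hence
the widest possible calibration domain).

The AOA threshold is Q75 + 1.5·IQR of the cross-validated training DI, with
quantiles under the type-7 (linear interpolation) convention — the threshold
value depends on the convention, so it is pinned and tested against a manual
quantile oracle. A pixel with DI exactly at the threshold is inside. Each
stock layer takes the AOA at its two bounding depths, averages the two 0/1
indicators, and is inside only when the average is exactly 1; averages of
0 or 0.5 are outside.

Expected error is calibrated by sorting CV samples by DI, computing RMSE in
sliding windows (default width 10% of the sample, minimum 20 — the window is
a documented knob; no standard window is established for this calibration), and
fitting an isotonic regression to the window-centre/window-RMSE pairs. The
isotonic fit realises the same shape constraint (monotone non-decreasing) as
a shape-constrained additive model while being dependency-free and exactly
testable; beyond the fitted DI range the prediction extrapolates flat. The
OCD-level expected errors at a layer's bounding depths are combined with the
identical trapezoid used for stocks, so expected error arrives in
Mg C ha⁻¹, the units of the predictions.

# The synthetic landscape

The generator is first-class, tested code, and its defaults are the study
conditions every acceptance property is measured under:

* **Covariates** are white noise smoothed with a Gaussian kernel of
  correlation length `smoothness` (degrees, default 0.1), standardized to
  mean 0/sd 1 over the marsh mask; categorical covariates are quantile
  slices of an additional smoothed field. Smoothing wraps circularly so the
  fields are stationary. Moran's I tests pin both limits (white noise and
  strong autocorrelation).
* **The marsh mask** is the top `mask_fraction` (default 0.4) quantile of
  another smoothed field, giving contiguous marsh patches. Pixel area uses
  one convention everywhere: (111.32 km · res) × (111.32 km · res · cos lat)
  × 100 ha at the pixel centre.
* **Truth** is linear-additive in the standardized covariates and depth,
  clipped at zero (default intercept 0.03 g C cm⁻³, effects of order
  ±0.002–0.008 per sd, depth effect −5 × 10⁻⁵ per cm — a nearly flat
  profile, as observed in marsh soils). Linearity makes parameter recovery
  and AOA behaviour analytically predictable while still exercising a
  nonlinear learner.
* **Sampling** draws 85% of 300 locations from 3 Gaussian clusters
  (sd 0.05°) and the rest uniformly over the mask; every location is sampled
  at layer centres {5, 15, 25, 45, 75, 95} cm and keeps its below-30 cm
  samples with probability 0.35. Cluster labels double as country/realm
  stand-ins for aggregation. Observation noise is additive Gaussian
  (default sd 0.004 g C cm⁻³, about 13% of the intercept); the noise
  structure of real OCD measurements is not reported anywhere we could
  anchor to, so `noise_sd` is a simulation knob, not an estimate.

What the generator does *not* emulate: real covariate marginals (tidal
amplitude, suspended matter, etc. beyond standardized fields), ocean/land
kernel infilling, measurement harmonisation across source datasets, or
shallow-soil truncation where marsh organic layers end above 30 cm. Passing
tests therefore demonstrate that the machinery is correct and behaves as
designed under known conditions — not that real-world skill equals the
synthetic numbers.

# Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere (`stats::quantile` default), pinned because
  the AOA threshold depends on it.
* Distance: haversine, R = 6371 km; DI distances: weighted Euclidean after
  scaling; cancellation residue in the squared-distance expansion is zapped
  at relative 1e-14 so DI is exactly 0 for identical predictor vectors.
* Nearest-pixel covariate lookup (no interpolation), matching per-pixel
  prediction semantics; cores on nodata pixels are dropped with a logged
  count, cores outside the grid are an error naming the location.
* Rows with missing covariates are dropped, never imputed.
* Collinearity screening is advisory (report, not drop); constant columns
  are reported as such rather than propagating NaN.
* Constant responses fit and predict exactly; all-zero responses predict 0;
  permuted responses score R² ≤ 0.05 under CV.
* Prediction over grids is chunked; output is bit-identical for any chunk
  size.
* Aggregation means are pixel-area-weighted by default (a `area_weighted`
  flag gives simple means — whether published global averages were weighted
  is unstated); the bivariate cell classes split at medians, echoed in the
  output attributes, since no thresholds are published.
* The 0–100 cm per-hectare mean is reported on the intersection of the two
  layers' AOAs (the deeper layer's AOA is consistently smaller); per-layer
  means use each layer's own AOA.

# Problem sizes

The default pipeline configuration runs a 64 × 64 pixel landscape
(0.02° resolution), 300 core locations (~1200 depth samples), 1000
prediction points for fold matching, and the full 5-fold CV with 300 trees;
it completes in a few seconds on one CPU. The acceptance properties use the
same scale with 10-seed replication where the property is statistical
(fold-matching superiority, AOA error discrimination). These sizes were
chosen as the smallest at which the clustered/dispersed geometry is
unambiguous; all formulas are resolution-free except pixel area.

One acceptance property deserves a note: "stock error below the
noise-implied bound as noise → 0" is operationalised as pixelwise stock RMSE
inside the AOA below 10% of the mean true stock at zero noise, since the
literal zero-noise bound (zero error) is unattainable for any finite
learner.

# Known limitations

* The k-NNDM variant searches a clustering ladder, not all partitions; it
  matches the enumeration optimum on separable scenes but is a heuristic in
  general (the achieved quality is always recorded).
* Isotonic calibration is piecewise-constant between knots (linearly
  interpolated at prediction); with few CV samples the error surface is
  coarse.
* The DI treats one-hot categorical dimensions as ordinary weighted axes;
  rare classes can dominate a pixel's DI if their indicator carries high
  importance.
* No quantile-forest prediction intervals, no conformal calibration, no
  leave-one-out NNDM, no spatio-temporal folds; depth profiles beyond 1 m
  are out of scope.
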