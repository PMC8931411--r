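---
title: "Cross-year training-sample transfer: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-year training-sample transfer: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Supervised crop-type mapping needs labeled training pixels for the season
being mapped, but field surveys are expensive and often unavailable for the
current year. Where planting structure is stable — most fields keep their
crop from one year to the next — labels collected in a *historical* year
still carry information about the *target* year. `croptransfer` turns each
historical sample into (at most) one new training sample for the target year
by exploiting **environmental similarity**: pixels within a small
neighborhood of a historical sample share growing conditions and management,
so the neighbor whose target-year spectral trajectory most resembles the
historical sample's trajectory most plausibly carries the same crop.

The pipeline is: fit per-pixel seasonal **feature curves** → score
neighbors by **dynamic-time-warping (DTW) similarity** → keep the best
neighbor per sample (**potential samples**) → screen them per crop by
**clustering + silhouette** (**generated samples**) → train a bagged
decision-tree ensemble → evaluate with confusion-matrix accuracies.

## Feature curves

Raw time series are irregular (cloud gaps shift the usable dates from year
to year) and noisy, so similarity is computed between *fitted curves*, not
raw observations. For each pixel and each feature — NIR reflectance, NDVI
`(NIR−Red)/(NIR+Red)` and the green/NIR NDWI `(Green−NIR)/(Green+NIR)`;
the green-band NDWI form is used because 4-band wide-swath imagers carry no
SWIR band — three candidate models are available, with the day of year `t`
as the axis:

* cubic polynomial: OLS on `(1, t, t², t³)`;
* 5-parameter harmonic: OLS on `(1, cos ωt, sin ωt, cos 2ωt, sin 2ωt)` with
  `ω = 2π/365` — the period is pinned to the annual cycle rather than
  estimated, since one growing season cannot identify it;
* Gaussian `a·exp(−((t−b)/c)²)`: Levenberg–Marquardt with moment-based
  starting values (implemented in C++; a fit that fails to improve is
  flagged unusable rather than silently kept).

Fit quality uses `SSE = Σ(yᵢ−fᵢ)²`, `SST = Σ(yᵢ−ȳ)²`, `R² = 1 − SSE/SST`
and `RMSE = √(SSE/m)`. RMSE is computed against the *predictions* `fᵢ`;
a definition against `ȳ` would merely duplicate `SST` and measure spread,
not fit. When `SST = 0` (constant observations) `R²` is defined as 1 for a
numerically perfect fit and 0 otherwise.

**Model selection** happens once per feature, not per pixel: every
historical sample's series is split 2:1, each candidate is fitted on the
two-thirds and scored on the held-out third, and the per-candidate test
`R²` is averaged over samples. The split is *chronologically stratified*
(every third observation in date order is held out): a random split would
make the winning model depend on a seed, and a chronological interleave
tests the curve across the whole season instead of extrapolating past its
end. Ties go to the lower test RMSE, then to the fixed order cubic →
harmonic → Gaussian. Per-pixel curves then always use the per-feature
winner, so any two pixels are compared on the same functional family.

Fitting needs at least 6 valid observations (the largest model has 5
unknowns); selection needs at least 9 so the held-out third has 3 points.
Only NIR, NDVI and NDWI feed the similarity stage: visible bands fit poorly
and are unstable between years, which makes them liabilities for curve
comparison.

## DTW similarity and potential samples

Sowing and harvest dates drift between years, so two trajectories of the
same crop are misaligned in time. Each fitted curve is resampled at
`n_points = 100` equal intervals over its own observed date span, and the
two resamplings are aligned by classic dynamic-programming DTW (local cost
`|aᵢ − bⱼ|`, match/insert/delete steps, no warping window, no internal
normalization). The distance maps to a similarity

    S = exp(−D / max(m, n)),   m = n = 100,

which is 1 at perfect alignment and decays toward 0. DTW is run per feature
and the per-feature similarities are averaged with equal weights; a true
multivariate DTW would entangle the per-feature curve models without a
principled weighting to justify it.

For each historical sample, every eligible pixel (≥ 6 valid dates per
feature) of the centered 5×5 target-year window — 80 m × 80 m at 16 m
pixels — is scored against the sample's historical curves, and **exactly
one** pixel, the arg-max of the aggregate similarity, becomes a potential
sample with the historical label. Keeping one pixel per sample preserves
the spatial distribution of the survey; ties break in row-major order
(deterministic, and immaterial once any noise is present). Samples whose
whole neighborhood is ineligible are skipped and logged. No minimum
similarity is imposed — screening is the quality gate.

The comparison runs historical-sample-curve against target-neighbor-curve
only; the historical center pixel is not re-fitted as a normalizer. That
keeps each historical sample's influence local and one-directional.

## Screening by clustering and silhouette

A potential sample can still carry the wrong label (rotation, boundary
pixels). Per crop, each potential sample is summarized by statistics of its
resampled curves — `(mean, sd, min, max, p25, p50, p75)` per feature,
concatenated over NIR/NDVI/NDWI into a 21-vector (raw time series cluster
poorly: date availability varies, and adjacent dates are highly
correlated). K-means (on per-dimension z-scores, 10 restarts, seeded) is
run for `k = 2 … min(20, n−1)`; each clustering is scored by the silhouette
coefficient

    a(i) = mean within-cluster distance,  b(i) = min over other clusters of
    the mean distance,  S(i) = (b−a)/max(a,b),  SC = mean S(i),

with `S(i) = 0` for singleton clusters; the `k` with the highest SC wins
(ties → smaller `k`), and only the largest cluster is retained (ties → the
cluster with the higher mean similarity). K-means is the canonical partner
of the silhouette criterion and is deterministic under seeding, which the
screening contract requires. Crops with fewer than 4 potential samples pass
through unscreened with a warning — clustering 3 points is theater.

## Classifier and evaluation

Training rows are fitted-curve evaluations on a fixed date grid (default
day 140…290 step 10 × three features = 48 columns), which makes rows
comparable even when the two years were observed on different dates. The
classifier is a bagged CART ensemble: 150 trees, each grown on a bootstrap
resample the size of the training set, each split choosing among
`⌊√p⌋` randomly drawn candidate features, Gini impurity, grown to purity,
majority vote. It is implemented in C++ inside the package (seeded
`std::mt19937`, so results are reproducible across platforms). A config
switch can add the visible bands for a six-feature variant.

Evaluation: a stratified, seeded 70/30 split of the target-year survey;
confusion matrix with rows = reference; `OA = trace/N`; per class
(one-vs-rest) producer's accuracy `PA = TP/(TP+FN)`, user's accuracy
`UA = TP/(TP+FP)`, `F1 = 2·PA·UA/(PA+UA)`; empty denominators give 0 and
are flagged. OA equals the count-weighted mean of per-class PA, which the
tests verify as an algebraic identity.

## The synthetic world

Real multi-year imagery with surveyed labels cannot ship with a package, so
every stage is exercised on simulated scenes with known truth
(`generate_scene_series()`):

* rectangular fields tile the grid (a requested field count is rounded up
  to the nearest `r × c` tiling); each field gets one crop per year, and
  rotation happens per field, not per pixel, so spatial autocorrelation
  matches the method's neighborhood assumption;
* each crop follows a double-logistic NDVI season (logistic green-up and
  senescence around a peak day). Defaults place the peaks at days 192–212
  with amplitudes 0.38–0.62, within reported ranges for northern
  maize/rice/soybean systems; "other" is a broad flat curve standing in for
  grass, forest and fallow. Rice additionally gets a pre-green-up paddy
  signal (NDVI depressed by 0.10, NDWI elevated) reflecting flooding;
* bands are *inverted* from NDVI/NDWI with a fixed red+NIR brightness and
  `blue = 0.85·green`, so bands and indices stay mutually consistent by
  construction; Gaussian noise (default SD 0.02 reflectance) is added per
  band and the result clipped to `[0, 1]`;
* observations sit on an 8-day grid over days 139–294 (a wide-swath revisit
  over the main growing season) and are knocked out tile-wise (16 px tiles)
  with probability `missing_rate`, mimicking spatially coherent cloud.
  Masked values are stored as `NaN` so any code path that read them would
  poison its output — the tests rely on this;
* each year draws one global phenology shift ~ `N(0, 10 days)`
  (inter-annual climate), and each **field** draws a sowing offset
  ~ `N(0, 3 days)` and an amplitude scale ~ `N(1, 0.05)` **once**, as a
  field identity shared by both years. Without field identities every field
  of a crop is statistically identical, per-crop feature clouds are pure
  noise blobs, and k-means screening splits them arbitrarily — a structure
  no real scene has. The 3-day/5% magnitudes reflect typical within-region
  sowing windows (about a week end to end) and field-to-field vigor
  differences; because identities persist across years, a pixel's two
  no-noise years still differ only by the global shift, which the transfer
  premise needs and a property test asserts.

What a green end-to-end test does **not** establish: performance on real
imagery. The simulator has no mixed pixels, no atmospheric residuals, no
within-field gradients, no irrigation failures, and its class geometry is
rectangular. The end-to-end criteria (same-crop selection rate, generated
purity, proportion preservation, OA within 10 points of a same-year
baseline) validate the *mechanics and internal consistency* of the method,
not a field-accuracy claim.

## Numerical and degenerate-case choices

* Pixel coordinates are 0-based `(row, col)`; geographic → pixel conversion
  floors to the containing cell.
* Reflectance is stored as float in `[0, 1]`; integer-scaled inputs are
  divided by a declared scale factor on read.
* The cubic is solved in a centered/scaled basis for conditioning and its
  coefficients are reported in the raw `(1, t, t², t³)` basis.
* Scenes and samples travel as plain-text grids + JSON sidecar, CSV and
  GeoJSON; a trained ensemble serializes to JSON with its column
  specification embedded, and prediction refuses a mismatched column spec
  outright.
* Atmospheric correction and orthorectification are upstream
  responsibilities; an optional `dn_to_radiance()` linear calibration
  (`Le = Gain·DN + Offset`, user-supplied coefficients) is the only
  radiometry included.
* All randomness is seeded per stage; the pipeline derives stage seeds from
  one global seed by fixed offsets and records them in the run manifest.

## Known limitations

* Transfer quality degrades when the inter-annual phenology shift is
  extreme: in the 20-seed end-to-end experiment, the two seeds that drew
  shifts beyond ±24 days showed clearly lower same-crop selection rates.
  This mirrors the method's premise — it transfers labels, it cannot
  conjure correspondence where seasons barely overlap.
* For the small heterogeneous "other" class (~10% of fields, ~25 potential
  samples per run) the silhouette optimum is not reliably at `k = 2`: its
  potential samples genuinely contain multi-field structure, and in 6 of 20
  seeds the SC peaked at `k ∈ 3…9`. The three main crops peak at 2 in
  17–19 of 20 seeds. Screening still behaves (the retained-fraction and
  purity properties hold); only the "SC is maximized at 2" regularity is
  class-size- and homogeneity-dependent.
* One historical sample yields at most one new sample, so the method can
  only preserve, never grow, the survey size per year; stratified-by-
  similarity extraction is deliberately out of scope.
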