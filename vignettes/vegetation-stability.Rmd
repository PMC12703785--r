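---
title: "Mapping vegetation stability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping vegetation stability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegstab)
```

## The problem

Annual peak vegetation productivity — typically measured as the annual
maximum of a vegetation index such as kernel NDVI, `kNDVI = tanh(NDVI^2)` —
can trend upward while its *stability* erodes. vegstab quantifies two
complementary stability dimensions per pixel of an annual raster time
series and tracks how they change:

* **Temporal variability** — the proportional variability index
  $$\mathrm{PV} = \frac{2}{n(n-1)} \sum_{i<j} \frac{|x_i - x_j|}{x_i + x_j},$$
  the mean relative difference over all pairs of years. PV is scale-free,
  bounded in $[0,1]$ for strictly positive series, exactly 0 for a constant
  series, and — unlike the coefficient of variation — neither assumes
  normality nor is dominated by single outliers. Higher PV = less stable.

* **Resilience** — lag-one autocorrelation
  $$\mathrm{AR} = \frac{\sum_{t=1}^{n-1}(x_t-\bar x)(x_{t+1}-\bar x)}
                       {\sum_{t=1}^{n}(x_t-\bar x)^2},$$
  bounded in $[-1,1]$ by Cauchy–Schwarz. Under critical-slowing-down (CSD)
  theory, rising AR signals slower recovery from perturbations and thus
  declining resilience.

Both metrics are computed on *detrended* series (OLS line removed; the
series mean is restored so values stay positive for PV, and AR is
mean-centered so the restoration is inert there). Without detrending, a
benign long-term greening trend would masquerade as both variability and
memory.

The change analysis applies a 15-year moving window (re-detrended within
each window), estimates the Theil–Sen slope of the windowed PV and AR
series per pixel (ΔPV, ΔAR), and combines the two into a composite
destabilization index: pixels with opposing trend signs are excluded, the
remaining slopes are normalized by their maximum absolute value, and the
two normalized values are summed, giving values in $[-2, 2]$. Positive =
destabilization hotspot, negative = stabilization coldspot. Pixels are also
classified into four stability regimes by the medians of PV and AR, and
into a five-state ecosystem typology by coupling the functioning trend
(Theil–Sen slope of the annual index, EF) with the stability trend (the
composite sign, ES). Finally, a gradient-boosted tree model with exact
TreeSHAP attributions relates the stability responses to climatic
background and climatic-stability predictors.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| window `W` | 15 | years | Just under half of a 40-year record: the first and last windows share no years, limiting spurious trend detection while retaining 26 windows for the slope. |
| `alpha` | 0.05 | — | Conventional significance level for trend tests. |
| regime threshold | 0.5 quantile | — | Median split of PV and AR over valid pixels; ties fall to the "low" side so "stable" is the closed cell and classification is deterministic. |
| `n_surrogate` | 100 | — | Surrogate replicates per pixel for window-trend significance; p-value resolution 1/101. |
| IDW `power`, `k` | 2, 10 | — | Conventional inverse-distance settings for station networks. |
| GBT defaults | lr 0.05, depth 8, 500 trees | — | The reference default configuration; the full 27-point grid (lr {0.01, 0.05, 0.1} × depth {4, 6, 8} × trees {300, 500, 700}) is searchable with 5-fold CV by RMSE. |
| split | 60/40 | — | Training/validation shares for the attribution model. |

## Significance of moving-window trends

This is the one place the package deliberately departs from the naive
recipe. Consecutive 15-year windows share 14 of 15 years, so a windowed
PV or AR series is an extremely smooth, strongly autocorrelated curve.
Applying the nominal Mann–Kendall test to it rejects a true null ~60% of
the time at α = 0.05 (measured by simulation); the Hamed–Rao
autocorrelation-corrected variance still rejects ~46%, because the ACF of a
26-point series cannot be estimated well enough to correct a correlation
this strong. The standard remedy in the early-warning-signals literature is
a surrogate-data null: fit a stationary AR(1) (mean, persistence, variance)
to each pixel's detrended annual series, simulate surrogate series, rerun
the full window-metric + Theil–Sen pipeline on them, and take the rank of
the observed |slope| as the p-value. This is calibrated by construction
(measured rejection 5.7% under white noise and 6.3% under AR(0.5)
stationarity) while retaining power (63% against a doubling variance ramp).
`trend_map()` defaults to this surrogate p; the nominal Mann–Kendall p is
still available (`p_method = "mk"`) and remains the right test for annual,
non-overlapping series such as the functioning (EF) trend, where its
measured type-I error is 4.8%.

## What the synthetic generator does (and does not) emulate

`simulate_stack()` draws, per pixel, `x_t = baseline + trend·(t−1) + e_t`
with `e_t` a stationary Gaussian AR(1) of persistence φ and stationary s.d.
`sigma_rel · baseline`. Defaults (40 years, baseline 0.5, φ = 0.3,
`sigma_rel` = 0.1) mimic a 40-year annual kNDVImax record: values near 0.5
with ~10% relative interannual noise and moderate memory. Zonal maps assign
per-zone (φ, `sigma_rel`, trend, baseline) so spatially clustered regimes
exist for recovery tests. Positivity (required by PV) is enforced by
redrawing a pixel's whole innovation sequence (up to 100 attempts) rather
than clipping — clipping would bias the variance the tests rely on; pixels
that never pass are masked. Each pixel gets its own RNG substream drawn
once from the master seed, so values are independent of grid traversal
order and bit-reproducible.

`simulate_drivers()` draws one smooth random field per climate covariate
(sums of random cosine plane waves, standardized) and a response that is a
known weighted sum plus Gaussian noise, giving the attribution stage a
recoverable dominant driver.

The generator does **not** emulate Landsat radiometry, cloud artifacts,
mixed pixels, spatially correlated noise beyond zone structure, or any
nonstationarity other than linear trends and parameter ramps constructed
explicitly in tests. A green test therefore establishes that the
*algorithms* are correct on data with known structure — not that the
regional percentages such a study reports are reproducible, which would require the
original satellite and climate archives.

## Numerical choices and edge cases

* **VPD**: the Tetens form
  `0.611 · exp(17.27 T / (T + 237.3)) · (1 − RH/100)` kPa. A literal
  `(100 − RH)` trailing factor would mix a kPa constant with a percentage
  and change units by 100×; the `/100` reading is the only dimensionally
  consistent one.
* **Degenerate pixels**: residual variance indistinguishable from
  floating-point noise (constant or perfectly linear series) gives PV = 0
  and AR = NA — never a silent 0 for AR — and such pixels are excluded from
  the regime medians.
* **PV validity**: any year-pair with `x_i + x_j ≤ 0` flags the pixel
  invalid; this signals non-positive data reaching an index defined for
  positive quantities.
* **Composite exclusion**: only a strict sign conflict excludes; zero
  slopes are non-opposing. Normalization constants are computed over
  *retained* pixels so an excluded extreme slope cannot dilate the scale
  (the alternative — normalizing before exclusion — is the other reading of
  the three-step recipe; retained-only is the conservative choice).
* **Theil–Sen / Mann–Kendall**: exact all-pairs median; MK uses the
  tie-corrected variance with continuity correction.
* **Moran's I**: rook contiguity, row-standardized weights, permutation p
  (999 draws by default) one-sided toward the observed side of
  `E[I] = −1/(N−1)`.
* **Grid-search ties**: broken toward fewer trees, then shallower depth
  (parsimony).
* **GBT determinism**: exact greedy splits with midpoint thresholds and
  first-best tie-breaking make training deterministic. Feature-permutation
  equivariance of SHAP importances holds up to exactly-tied split gains at
  tiny leaves (measured effect < 1% of an importance share).
* **Ecosystem states**: EF significant up + ES improving (composite < 0) →
  ideal; EF up + ES degrading → acceptable; EF down + ES improving → poor;
  EF down + ES degrading → abysmal; non-significant EF, excluded ES, or
  zero composite → unknown. The mapping is a reconstruction from the
  qualitative description of the typology and is user-configurable via
  `state_table`.

## Design decisions where the design was open

* Windowed metrics are **re-detrended within each window** rather than
  inheriting one global detrend: a window is meant to detect local
  inflections, which residual global trend would contaminate.
* Regime medians are computed over all valid (unmasked, non-degenerate)
  pixels of the supplied stack — the package has no land-cover concept, so
  "vegetated" filtering is the caller's responsibility via the mask.
* ΔAR/ΔPV slopes are in metric units **per year** (windows advance one
  year per step); only their sign enters the composite and state maps, so
  the unit convention is cosmetic downstream.
* The attribution split is plain random over sampled pixels (no spatial
  blocking). With spatially autocorrelated fields this inflates validation
  R²; the recovery tests measure ranking, not honest predictive skill.
* Raster interchange uses ESRI ASCII grids plus a JSON year sidecar and
  long CSV — plain-text equivalents of the GeoTIFF outputs a GDAL-backed
  deployment would write; georeference and NoData semantics are preserved.

## Limitations

* The surrogate null assumes the stationary alternative is AR(1) Gaussian;
  heavier-tailed or long-memory noise would need a different surrogate
  family.
* PV requires strictly positive data; indices that cross zero (e.g. raw
  NDVI anomalies) must be offset or rescaled first.
* TreeSHAP attributions are correlational; no causal claims follow.
* The small-sample AR estimator is biased low (≈ −(1 + 4φ)/n, plus an
  additional detrending bias); cross-pixel *comparisons* are unaffected,
  but absolute AR values at n = 40 underestimate φ.
* All per-pixel computations are exact and tile-independent; only the
  regime medians, composite normalization constants, and Moran's I are
  global quantities.
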