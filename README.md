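# vegstab

Pixel-wise assessment of **vegetation stability** from annual
vegetation-index raster time series, for ecologists and remote-sensing
analysts who want to know not just whether a landscape is greening, but
whether that productivity is becoming more or less *reliable*.

## What it computes

Given a `[row, col, year]` stack of a strictly positive annual index
(typically annual-maximum kernel NDVI, `kNDVI = tanh(NDVI²)`), vegstab
derives, per pixel:

* **Proportional variability**
  `PV = 2/(n(n−1)) · Σ_{i<j} |x_i − x_j| / (x_i + x_j)` — scale-free
  temporal variability in `[0, 1]`; higher = less stable.
* **Lag-one autocorrelation**
  `AR = Σ (x_t − x̄)(x_{t+1} − x̄) / Σ (x_t − x̄)²` — temporal memory in
  `[−1, 1]`; under critical-slowing-down theory, higher AR = slower
  recovery = lower resilience.

Both are computed on linearly detrended series (mean restored). On top of
these come:

* 15-year **moving-window** PV/AR series and their **Theil–Sen trends**
  (ΔPV, ΔAR), with significance from a per-pixel AR(1) **surrogate null**
  (the nominal Mann–Kendall test badly over-rejects on overlapping
  windows; see the methods vignette);
* the **composite ΔAR PV index**: exclude opposing-sign pixels, normalize
  each slope field by its max |value| over retained pixels, sum — values
  in `[−2, 2]`, positive = destabilization **hotspot**, negative =
  **coldspot**;
* median-threshold **stability regimes**
  (stable / unstable / two intermediate quadrants);
* a five-state **ecosystem typology** (ideal / acceptable / poor /
  abysmal / unknown) coupling the functioning trend (Theil–Sen slope of
  the annual index) with the composite stability trend;
* **Moran's I** with permutation p for spatial-clustering checks;
* **driver attribution**: gradient-boosted regression trees (squared
  loss, exact greedy splits; defaults learning_rate 0.05, max_depth 8,
  500 trees; optional 27-point grid search with 5-fold CV) explained by
  exact path-dependent **TreeSHAP** — per-feature importances as mean
  |Shapley value| percentages, category sums, and dependence curves.

A synthetic-data module generates AR(1) raster stacks and smooth covariate
fields with known persistence, variability, trends, zones and a dominant
driver, so the entire chain is verifiable without satellite data. Rasters
are read/written as plain-text ESRI ASCII grids (+ JSON year sidecar) and
long CSV.

## Worked example

End-to-end pipeline on a simulated 20 × 20 × 40 stack:

```r
library(vegstab)
cfg <- pipeline_config(
  sim = sim_config(n_years = 40, n_rows = 20, n_cols = 20,
                   phi = 0.3, sigma_rel = 0.1, seed = 42),
  window = 15, seed = 42)
res <- run_pipeline(cfg)
#> [stack] 20 x 20 x 40
#> [stability] 400 valid pixels
#> [trends] 26 windows; hotspot 122 / coldspot 123 / excluded 155
res$manifest$regime_thresholds
#> $pv 0.0544  $ar 0.2203
```

The stack is stationary by construction, so hotspots and coldspots are
split roughly evenly (122 vs 123 of 400 pixels; 155 excluded for opposing
trend signs) — no destabilization signal, as it should be. The regime
thresholds are the medians of PV (0.054) and AR (0.220) across valid
pixels; at φ = 0.3 and 10% relative noise, a 40-year detrended series
indeed has small PV and memory biased below φ by the small-sample AR bias
≈ (1 + 4φ)/n.

Driver attribution with a known dominant driver (radiation, weight 0.8 vs
≤ 0.2 for the rest, noise s.d. 0.1):

```r
cfg <- sim_config(n_rows = 30, n_cols = 30, seed = 1)
drv <- simulate_drivers(cfg, driver_spec(
  weights = c(radiation = 0.8, temperature = 0.15, precipitation = 0.1,
              soil_moisture = 0.15, vpd = 0.2),
  noise_sd = 0.1))
tbl <- build_feature_table(drv$covariates, drv$response, seed = 1)
mod <- fit_stability_model(tbl)      # reference defaults
att <- shapley_attribution(mod, tbl, max_samples = 500, seed = 1)
mod$r2_valid
#> 0.973
round(sort(att$importance, decreasing = TRUE), 1)
#>     radiation soil_moisture           vpd   temperature precipitation
#>          61.5          16.5          11.8           8.6           1.6
```

The model explains 97% of held-out variance and TreeSHAP puts the planted
driver first by a wide margin; its dependence curve
(`dependence_export(att, "radiation")`) is monotone increasing, matching
the linear ground truth.

## Command line

```sh
exec/stability simulate --out out/ --seed 3
exec/stability metrics  --in out/kndvi_years.json --out maps/
exec/stability run      --out results/ --seed 3
exec/stability attribute --table features.csv --out attr/
```

## Package layout

* `R/` — synthetic data, preprocessing (kNDVI, VPD, IDW, resampling,
  detrending), stability metrics, trends/hotspots/states, attribution,
  I/O, pipeline, CLI
* `src/boost.cpp` — gradient-boosted trees + exact TreeSHAP (Rcpp)
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
* `vignettes/vegetation-stability.Rmd` — methods and design notes
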