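Package: vegstab
Title: Vegetation Stability Mapping from Annual Vegetation-Index Time Series
Version: 0.1.0
Authors@R: person("Vegstab", "Developers", email = "vegstab@example.org", role = c("aut", "cre"))
Description: Pixel-wise assessment of vegetation stability from annual
    vegetation-index raster time series. Computes temporal variability
    (proportional variability, PV) and resilience (lag-one autocorrelation,
    AR) maps, 15-year moving-window Theil-Sen trends with calibrated
    significance, a composite destabilization-hotspot index, median-threshold
    stability regimes, a five-state ecosystem typology coupling functioning
    and stability, and an interpretable driver-attribution stage based on
    gradient-boosted trees with exact Shapley-value explanations. Includes a
    synthetic-data generator with known persistence, variability, trend and
    driver structure so the whole chain is testable without satellite data,
    plus preprocessing utilities (kernel NDVI, vapor pressure deficit,
    inverse-distance-weighted station interpolation, nearest-neighbor
    resampling, linear detrending) and plain-text raster I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
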