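#' Kernel NDVI transform
#'
#' `kNDVI = tanh(NDVI^2)`. The squared-then-tanh kernel keeps sensitivity in
#' high-biomass canopies where plain NDVI saturates; output lies in
#' `[0, tanh(1)]` and is even in NDVI.
#'
#' @param ndvi numeric vector/matrix/array with values in `[-1, 1]`
#'   (`NA` allowed and propagated).
#' @return same shape, `tanh(ndvi^2)`.
#' @export
kndvi <- function(ndvi) {
  bad <- is.finite(ndvi) & abs(ndvi) > 1
  if (any(bad))
    stop("NDVI values outside [-1, 1]; input looks unscaled")
  tanh(ndvi^2)
}

#' Annual maximum composite
#'
#' Reduces a per-observation stack to one layer per year by taking the
#' maximum over valid (finite) observations, the standard proxy for peak
#' growing-season activity. Pixel-years with no valid observation are left
#' `NA` (never silently 0).
#'
#' @param obs 3-D array `[row, col, observation]`.
#' @param obs_years integer vector of the year of each observation slice.
#' @param ... passed to [raster_stack()] (georeference).
#' @return a [raster_stack()] with one layer per distinct year. Pixels with
#'   a missing year are excluded from the stack mask.
#' @export
annual_max_composite <- function(obs, obs_years, ...) {
  if (missing(obs_years) || is.null(obs_years))
    stop("observation timestamps (obs_years) are required")
  if (length(dim(obs)) != 3L || dim(obs)[3L] != length(obs_years))
    stop("obs must be [row, col, observation] matching obs_years")
  years <- sort(unique(as.integer(obs_years)))
  d <- dim(obs)
  out <- array(NA_real_, c(d[1L], d[2L], length(years)))
  for (k in seq_along(years)) {
    sl <- obs[, , obs_years == years[k], drop = FALSE]
    mx <- apply(sl, c(1L, 2L), function(v) {
      v <- v[is.finite(v)]
      if (length(v)) max(v) else NA_real_
    })
    out[, , k] <- mx
  }
  raster_stack(out, years = years, ...)
}

#' Vapor pressure deficit (Tetens)
#'
#' `VPD = 0.611 * exp(17.27 T / (T + 237.3)) * (1 - RH/100)` in kPa, with
#' air temperature `T` in degrees C and relative humidity `RH` in percent.
#'
#' @param temp air temperature, degrees C.
#' @param rh relative humidity, percent in `[0, 100]`.
#' @return VPD in kPa, same shape as the inputs.
#' @export
vpd <- function(temp, rh) {
  bad <- is.finite(rh) & (rh < 0 | rh > 100)
  if (any(bad)) stop("relative humidity must lie in [0, 100] percent")
  es <- 0.611 * exp(17.27 * temp / (temp + 237.3))
  es * (1 - rh / 100)
}

#' Inverse-distance-weighted interpolation of station values
#'
#' Interpolates point observations onto a grid with weights
#' `w_i = d_i^-power` over the `k` nearest stations (all stations if fewer
#' than `k` exist). A cell coinciding with a station returns that station's
#' value exactly. Distances are Euclidean in the projected plane; ties in
#' the k-nearest set are broken by station index.
#'
#' @param stations data.frame with columns `x`, `y`, `value`.
#' @param grid list with `n_rows`, `n_cols`, `xll`, `yll`, `cellsize`
#'   (cell centers at `xll + (col - 0.5) * cellsize` etc., row 1 on top).
#' @param power IDW exponent (default 2).
#' @param k number of neighbors (default 10).
#' @return matrix `[n_rows, n_cols]` of interpolated values.
#' @export
idw_interpolate <- function(stations, grid, power = 2, k = 10L) {
  stopifnot(all(c("x", "y", "value") %in% names(stations)),
            nrow(stations) >= 1L, all(is.finite(stations$value)))
  dup <- duplicated(stations[c("x", "y")])
  if (any(dup)) {
    key <- interaction(stations$x, stations$y, drop = TRUE)
    if (any(tapply(stations$value, key, function(v) length(unique(v)) > 1L)))
      stop("duplicate station coordinates with conflicting values")
    stations <- stations[!dup, , drop = FALSE]
  }
  k <- min(k, nrow(stations))
  cx <- grid$xll + (seq_len(grid$n_cols) - 0.5) * grid$cellsize
  cy <- grid$yll + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cellsize
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) for (cc in seq_len(grid$n_cols)) {
    d <- sqrt((stations$x - cx[cc])^2 + (stations$y - cy[r])^2)
    near <- order(d)[seq_len(k)]        # order() breaks ties by index
    if (d[near[1L]] == 0 || k == 1L) {
      out[r, cc] <- stations$value[near[1L]]
    } else {
      w <- d[near]^(-power)
      out[r, cc] <- sum(w * stations$value[near]) / sum(w)
    }
  }
  out
}

#' Nearest-neighbor resampling of a raster layer
#'
#' Each target cell takes the value of the source cell whose center is
#' nearest to the target cell center (same coordinate frame); `NA` cells
#' propagate.
#'
#' @param layer source matrix.
#' @param src,dst grid lists (`n_rows`, `n_cols`, `xll`, `yll`, `cellsize`).
#' @return matrix on the target grid.
#' @export
resample_nearest <- function(layer, src, dst) {
  sx <- src$xll + (seq_len(src$n_cols) - 0.5) * src$cellsize
  sy <- src$yll + (src$n_rows - seq_len(src$n_rows) + 0.5) * src$cellsize
  tx <- dst$xll + (seq_len(dst$n_cols) - 0.5) * dst$cellsize
  ty <- dst$yll + (dst$n_rows - seq_len(dst$n_rows) + 0.5) * dst$cellsize
  if (max(tx) < min(sx) - src$cellsize / 2 || min(tx) > max(sx) + src$cellsize / 2 ||
      max(ty) < min(sy) - src$cellsize / 2 || min(ty) > max(sy) + src$cellsize / 2)
    stop("source and target extents are disjoint")
  nearest <- function(p, centers) vapply(p, function(v) which.min(abs(centers - v)), 0L)
  ci <- nearest(tx, sx)
  ri <- nearest(ty, sy)
  layer[ri, ci, drop = FALSE]
}

#' Linear detrending of a pixel time series
#'
#' Removes the OLS line fit on (year index, value); with
#' `restore_mean = TRUE` (the default used ahead of the stability metrics)
#' the series mean is added back so residuals stay strictly positive for
#' well-behaved inputs, as required by the proportional-variability index.
#' An all-identical series is returned unchanged but flagged degenerate
#' (attribute `degenerate`): its AR is undefined and its PV is 0.
#'
#' @param x numeric series, length >= 3.
#' @param restore_mean add the series mean back onto the residuals.
#' @return residual series (same length) with attribute `degenerate`.
#' @export
detrend_linear <- function(x, restore_mean = TRUE) {
  if (length(x) < 3L) stop("series must have length >= 3")
  if (anyNA(x) || !all(is.finite(x))) stop("series must be finite")
  if (length(unique(x)) == 1L) {
    out <- if (restore_mean) x else rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  t <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, t), x)
  r <- unname(fit$residuals)
  out <- if (restore_mean) r + mean(x) else r
  attr(out, "degenerate") <- stats::var(r) == 0
  out
}
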