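#' Proportional variability (PV)
#'
#' `PV = 2 / (n (n - 1)) * sum_{i<j} |x_i - x_j| / (x_i + x_j)`: the mean
#' relative difference over all pairs of years. Scale-free, bounded in
#' `[0, 1]` for strictly positive data, exactly 0 for a constant series;
#' higher values mean larger interannual fluctuation, i.e. lower temporal
#' stability.
#'
#' @param x numeric series with `n >= 2`; every pair must satisfy
#'   `x_i + x_j > 0` (strict positivity suffices).
#' @return PV in `[0, 1]`, or `NA` if a pair sum is non-positive (a flag
#'   that non-positive data reached the index).
#' @export
proportional_variability <- function(x) {
  n <- length(x)
  if (n < 2L || anyNA(x)) return(NA_real_)
  xs <- sort(x)
  if (xs[1L] + xs[2L] <= 0) return(NA_real_)
  if (xs[1L] == xs[n]) return(0)
  s <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    s <- s + sum(abs(x[i] - x[j]) / (x[i] + x[j]))
  }
  2 / (n * (n - 1)) * s
}

#' Lag-one autocorrelation (AR)
#'
#' `AR = sum_{t=1}^{n-1} (x_t - xbar)(x_{t+1} - xbar) / sum_t (x_t - xbar)^2`.
#' Under critical-slowing-down theory a rising AR signals slower recovery
#' from perturbations, i.e. eroding resilience. Bounded in `[-1, 1]` by
#' Cauchy-Schwarz.
#'
#' @param x numeric series, `n >= 3`, non-zero variance.
#' @return AR in `[-1, 1]`, or `NA` for a zero-variance (degenerate) series
#'   -- never a silent 0.
#' @export
lag1_autocorrelation <- function(x) {
  n <- length(x)
  if (n < 3L || anyNA(x)) return(NA_real_)
  z <- x - mean(x)
  den <- sum(z^2)
  if (den == 0) return(NA_real_)
  sum(z[-n] * z[-1L]) / den
}

# ---- vectorized internals over a (n_series x n_years) matrix ----

# OLS-detrend every row; optionally restore each row's mean.
detrend_rows <- function(Y, restore_mean = TRUE) {
  W <- ncol(Y)
  t <- seq_len(W)
  X <- cbind(1, t)
  P <- X %*% solve(crossprod(X)) %*% t(X)
  R <- Y - Y %*% t(P)
  if (restore_mean) R + rowMeans(Y) else R
}

pv_rows <- function(Y) {
  W <- ncol(Y)
  s <- numeric(nrow(Y))
  bad <- rep(FALSE, nrow(Y))
  for (i in seq_len(W - 1L)) for (j in (i + 1L):W) {
    den <- Y[, i] + Y[, j]
    bad <- bad | den <= 0
    s <- s + abs(Y[, i] - Y[, j]) / den
  }
  out <- 2 / (W * (W - 1)) * s
  out[bad] <- NA_real_
  out
}

ar_rows <- function(Y) {
  Z <- Y - rowMeans(Y)
  den <- rowSums(Z^2)
  num <- rowSums(Z[, -ncol(Z), drop = FALSE] * Z[, -1L, drop = FALSE])
  ifelse(den > 0, num / den, NA_real_)
}

#' Per-pixel stability map (PV and AR)
#'
#' Detrends each valid pixel's series (OLS line removed, mean restored --
#' the restored mean keeps values positive for PV; AR is mean-centered and
#' unaffected) and computes both stability metrics. Degenerate pixels
#' (zero variance after detrending) get `PV = 0` and `AR = NA` and are
#' flagged so threshold computations can exclude them.
#'
#' @param stack a [raster_stack()] with >= 3 years.
#' @param detrend remove the linear trend first (the standard protocol).
#' @return object of class `stability_map`: matrices `pv`, `ar`, logical
#'   `valid` (metrics defined) and `degenerate`.
#' @export
stability_map <- function(stack, detrend = TRUE) {
  stopifnot(inherits(stack, "raster_stack"))
  if (n_years(stack) < 3L) stop("stack must have >= 3 years")
  Y <- stack_matrix(stack)
  ok <- as.vector(stack$mask)
  pv <- ar <- rep(NA_real_, nrow(Y))
  degen <- rep(FALSE, nrow(Y))
  if (any(ok)) {
    Yv <- Y[ok, , drop = FALSE]
    R <- if (detrend) detrend_rows(Yv) else Yv
    dg <- rows_degenerate(R, Yv)
    pvv <- pv_rows(R)
    arv <- ar_rows(R)
    pvv[dg] <- 0
    arv[dg] <- NA_real_
    pv[ok] <- pvv; ar[ok] <- arv; degen[ok] <- dg
  }
  valid <- ok & (is.finite(pv) | degen)
  structure(list(pv = pixel_matrix(pv, stack),
                 ar = pixel_matrix(ar, stack),
                 valid = pixel_matrix(valid, stack),
                 degenerate = pixel_matrix(degen, stack)),
            class = "stability_map")
}

#' Moving-window stability metrics
#'
#' Slides a `W`-year window (default: 15 years over a 40-year record,
#' short of half the record so the first and last windows stay independent)
#' across each pixel's series; each window is re-detrended before PV and AR
#' are computed, so residual long-term trends cannot masquerade as
#' stability change. Windows are anchored at their center year.
#'
#' @param stack a [raster_stack()] with `n_years >= W + 2` (so at least 3
#'   windows exist for a trend).
#' @param W window length in years.
#' @return object of class `window_series`: arrays `pv` and `ar` of shape
#'   `[row, col, n_windows]`, `anchors` (center years), `W`, and the annual
#'   pixel matrix retained for surrogate-based significance testing.
#' @export
moving_window_metrics <- function(stack, W = 15L) {
  stopifnot(inherits(stack, "raster_stack"))
  ny <- n_years(stack)
  if (W >= ny) stop("window length W must be < n_years")
  if (ny < W + 2L) stop("need n_years >= W + 2 for a trend over windows")
  n_win <- ny - W + 1L
  Y <- stack_matrix(stack)
  ok <- as.vector(stack$mask)
  d <- dim(stack$values)
  pv <- ar <- array(NA_real_, c(d[1L], d[2L], n_win))
  Yv <- Y[ok, , drop = FALSE]
  for (s in seq_len(n_win)) {
    Yw <- Yv[, s:(s + W - 1L), drop = FALSE]
    R <- detrend_rows(Yw)
    dg <- rows_degenerate(R, Yw)
    p <- pv_rows(R); a <- ar_rows(R)
    p[dg] <- 0; a[dg] <- NA_real_
    full_p <- full_a <- rep(NA_real_, nrow(Y))
    full_p[ok] <- p; full_a[ok] <- a
    pv[, , s] <- pixel_matrix(full_p, stack)
    ar[, , s] <- pixel_matrix(full_a, stack)
  }
  anchors <- stack$years[seq_len(n_win) + (W - 1L) %/% 2L]
  structure(list(pv = pv, ar = ar, anchors = anchors, W = as.integer(W),
                 annual = Y, mask = stack$mask, years = stack$years),
            class = "window_series")
}

# Residual variance indistinguishable from floating-point noise relative to
# the magnitude of the original series: constant or perfectly linear pixels.
rows_degenerate <- function(R, Y) {
  res_ss <- rowSums((R - rowMeans(R))^2)
  scale_ss <- rowMeans(Y^2) * ncol(R)
  res_ss <= 1e-20 * pmax(scale_ss, .Machine$double.xmin)
}

#' Classify pixels into stability regimes
#'
#' Splits valid pixels at the medians (50th percentiles) of PV and AR:
#' low PV & low AR = stable; high PV & high AR = unstable; the two mixed
#' quadrants are intermediate. Values exactly at a median count as "low"
#' (deterministic closed stable cell). Degenerate pixels are excluded from
#' the medians and left unclassified.
#'
#' @param map a [stability_map()].
#' @return object of class `regime_map`: integer matrix `code`
#'   (1 = stable, 2 = unstable, 3 = high-PV/low-AR, 4 = low-PV/high-AR,
#'   0 = invalid), the two `thresholds`, and the label table.
#' @export
classify_regimes <- function(map) {
  stopifnot(inherits(map, "stability_map"))
  use <- map$valid & !map$degenerate & is.finite(map$pv) & is.finite(map$ar)
  if (!any(use)) stop("no valid pixels to classify")
  med_pv <- stats::median(map$pv[use])
  med_ar <- stats::median(map$ar[use])
  code <- matrix(0L, nrow(map$pv), ncol(map$pv))
  lo_pv <- map$pv <= med_pv
  lo_ar <- map$ar <= med_ar
  code[use & lo_pv & lo_ar] <- 1L
  code[use & !lo_pv & !lo_ar] <- 2L
  code[use & !lo_pv & lo_ar] <- 3L
  code[use & lo_pv & !lo_ar] <- 4L
  structure(list(code = code,
                 thresholds = c(pv = med_pv, ar = med_ar),
                 labels = c(`1` = "stable", `2` = "unstable",
                            `3` = "moderate_highPV_lowAR",
                            `4` = "moderate_lowPV_highAR", `0` = "invalid")),
            class = "regime_map")
}
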