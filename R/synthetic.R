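#' Simulation configuration for synthetic vegetation-index stacks
#'
#' Describes a grid of pixels whose annual series follow
#' `x_t = baseline + trend * (t - 1) + e_t`, where `e_t` is a stationary
#' Gaussian AR(1) process with persistence `phi` and stationary standard
#' deviation `sigma_rel * baseline`. The defaults mirror the kind of record the
#' package emulates: a 40-year annual record of a bounded, strictly positive
#' vegetation index (annual-maximum kernel NDVI) with moderate interannual
#' noise.
#'
#' Zonal structure: `zone_map` (integer matrix, same shape as the grid)
#' assigns each pixel a row of `zones`, a data.frame with columns among
#' `zone`, `phi`, `sigma_rel`, `trend`, `baseline`; unspecified columns fall
#' back to the scalar defaults.
#'
#' @param n_years number of annual layers (>= 3).
#' @param n_rows,n_cols grid dimensions.
#' @param baseline mean index level (> 0).
#' @param phi AR(1) persistence, in (-1, 1).
#' @param sigma_rel stationary noise s.d. relative to `baseline` (>= 0).
#' @param trend additive per-year slope.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   stacks.
#' @param zone_map optional integer matrix of zone labels.
#' @param zones optional data.frame of per-zone parameters (see Details).
#' @return `sim_config` object (validated list).
#' @export
sim_config <- function(n_years = 40L, n_rows = 20L, n_cols = 20L,
                       baseline = 0.5, phi = 0.3, sigma_rel = 0.1,
                       trend = 0, seed = 1L, zone_map = NULL, zones = NULL) {
  num_ok <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  if (!num_ok(n_years) || n_years < 3) stop("n_years must be >= 3")
  if (!num_ok(n_rows) || n_rows < 1 || !num_ok(n_cols) || n_cols < 1)
    stop("grid dimensions must be positive")
  if (!num_ok(baseline) || baseline <= 0) stop("baseline must be > 0")
  if (!num_ok(phi) || abs(phi) >= 1) stop("phi must lie in (-1, 1)")
  if (!num_ok(sigma_rel) || sigma_rel < 0) stop("sigma_rel must be >= 0")
  if (!num_ok(trend)) stop("trend must be a finite number")
  if (!num_ok(seed)) stop("seed must be a finite integer")
  if (!is.null(zone_map)) {
    zone_map <- as.matrix(zone_map)
    if (!identical(dim(zone_map), c(as.integer(n_rows), as.integer(n_cols))))
      stop("zone_map dimensions must match the grid")
    if (is.null(zones) || !all(unique(as.vector(zone_map)) %in% zones$zone))
      stop("every zone_map label needs a row in `zones`")
  }
  structure(list(n_years = as.integer(n_years), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), baseline = baseline, phi = phi,
                 sigma_rel = sigma_rel, trend = trend, seed = as.integer(seed),
                 zone_map = zone_map, zones = zones),
            class = "sim_config")
}

# Per-pixel parameter lookup honoring zone_map.
pixel_params <- function(config, row, col) {
  p <- config[c("baseline", "phi", "sigma_rel", "trend")]
  if (!is.null(config$zone_map)) {
    z <- config$zone_map[row, col]
    zr <- config$zones[match(z, config$zones$zone), , drop = FALSE]
    for (f in intersect(names(p), names(zr)))
      if (is.finite(zr[[f]])) p[[f]] <- zr[[f]]
  }
  p
}

# One RNG sub-seed per pixel, drawn from the config seed in a single pass so
# a pixel's stream never depends on grid traversal order.
pixel_seeds <- function(config) {
  n <- config$n_rows * config$n_cols
  withr_seed <- config$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate one pixel's annual series
#'
#' Draws the AR(1) series described in [sim_config()]. Positivity (required
#' by the proportional-variability index) is enforced by rejection: the whole
#' innovation sequence is redrawn (up to 100 attempts) rather than clipped,
#' so accepted series keep an undistorted variance. A pixel that never passes
#' returns all-`NA` (it will be masked by [simulate_stack()]).
#'
#' @param config a [sim_config()].
#' @param pixel `c(row, col)` grid index.
#' @return numeric vector of length `n_years`, strictly positive, or all-`NA`.
#' @export
simulate_pixel_series <- function(config, pixel = c(1L, 1L)) {
  stopifnot(inherits(config, "sim_config"), length(pixel) == 2L)
  seeds <- pixel_seeds(config)
  idx <- (pixel[2L] - 1L) * config$n_rows + pixel[1L]
  draw_pixel_series(config, pixel[1L], pixel[2L], seeds[idx])
}

draw_pixel_series <- function(config, row, col, seed) {
  p <- pixel_params(config, row, col)
  n <- config$n_years
  s <- p$sigma_rel * p$baseline          # stationary sd
  det <- p$baseline + p$trend * (seq_len(n) - 1)
  if (s == 0) return(det)                 # noiseless limit
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  innov_sd <- s * sqrt(1 - p$phi^2)
  for (attempt in seq_len(100L)) {
    e <- numeric(n)
    e[1L] <- rnorm(1L, 0, s)
    if (n > 1L) {
      z <- rnorm(n - 1L, 0, innov_sd)
      for (t in 2:n) e[t] <- p$phi * e[t - 1L] + z[t - 1L]
    }
    x <- det + e
    if (all(x > 0)) return(x)
  }
  rep(NA_real_, n)
}

#' Simulate a full raster stack
#'
#' Applies [simulate_pixel_series()] to every pixel (honoring `zone_map`),
#' masking pixels whose series failed the positivity rule. Year labels run
#' `1` to `n_years` offset to a nominal start year.
#'
#' @param config a [sim_config()].
#' @param start_year calendar label of the first layer (cosmetic).
#' @return a [raster_stack()].
#' @export
simulate_stack <- function(config, start_year = 1984L) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- pixel_seeds(config)
  nr <- config$n_rows; nc <- config$n_cols; ny <- config$n_years
  vals <- array(NA_real_, c(nr, nc, ny))
  for (col in seq_len(nc)) for (row in seq_len(nr)) {
    idx <- (col - 1L) * nr + row
    vals[row, col, ] <- draw_pixel_series(config, row, col, seeds[idx])
  }
  raster_stack(vals, years = start_year + seq_len(ny) - 1L)
}

#' Driver specification for synthetic attribution experiments
#'
#' Names the climate covariates and the linear weights with which they shape
#' a simulated stability response. Exactly one covariate (the largest
#' absolute weight) is the dominant driver the attribution stage should
#' recover.
#'
#' @param weights named numeric vector (>= 2 covariates, not all zero);
#'   conventional names are `temperature`, `precipitation`, `radiation`,
#'   `soil_moisture`, `vpd`.
#' @param noise_sd s.d. of additive Gaussian noise on the response (>= 0).
#' @return `driver_spec` object.
#' @export
driver_spec <- function(weights = c(radiation = 0.8, temperature = 0.15,
                                    precipitation = 0.1, soil_moisture = 0.15,
                                    vpd = 0.2),
                        noise_sd = 0.1) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be a named vector")
  if (length(weights) < 2L) stop("need >= 2 covariates")
  if (all(weights == 0)) stop("weights must not all be zero")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  aw <- abs(weights)
  if (sum(aw == max(aw)) != 1L)
    stop("exactly one covariate must carry the largest |weight|")
  structure(list(weights = weights, noise_sd = noise_sd,
                 dominant = names(weights)[which.max(aw)]),
            class = "driver_spec")
}

# Smooth standardized random field: a sum of random cosine plane waves over
# the unit square, standardized to mean 0 / sd 1 across the grid.
smooth_field <- function(nr, nc, n_waves = 6L) {
  xs <- (seq_len(nc) - 0.5) / nc
  ys <- (seq_len(nr) - 0.5) / nr
  f <- matrix(0, nr, nc)
  for (k in seq_len(n_waves)) {
    u <- runif(1, 0.5, 2.5); v <- runif(1, 0.5, 2.5)
    ph <- runif(1, 0, 2 * pi); a <- rnorm(1)
    f <- f + a * cos(2 * pi * (outer(ys, xs, function(y, x) u * x + v * y)) + ph)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Simulate covariate fields and a known stability response
#'
#' Draws one smooth spatial field per covariate (long-term climate means are
#' spatially smooth at landscape scale) and a response
#' `sum_j w_j * z_j + N(0, noise_sd)` from standardized fields `z_j`, so the
#' attribution stage has a recoverable ground truth. Both the noisy response
#' and the noiseless linear predictor are returned.
#'
#' @param config a [sim_config()] (supplies grid shape and seed).
#' @param spec a [driver_spec()].
#' @return list with `covariates` (named list of matrices), `response`,
#'   `response_true` (noiseless), and `spec`.
#' @export
simulate_drivers <- function(config, spec = driver_spec()) {
  stopifnot(inherits(config, "sim_config"), inherits(spec, "driver_spec"))
  nr <- config$n_rows; nc <- config$n_cols
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 777L)
  covs <- lapply(sort(names(spec$weights)), function(nm) smooth_field(nr, nc))
  names(covs) <- sort(names(spec$weights))
  true <- Reduce(`+`, Map(function(nm) spec$weights[[nm]] * covs[[nm]],
                          names(covs)))
  resp <- true + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  list(covariates = covs[names(spec$weights)], response = resp,
       response_true = true, spec = spec)
}
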