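#' Theil-Sen slope
#'
#' Median of all pairwise slopes `(y_j - y_i) / (t_j - t_i)`, `i < j`:
#' robust to outliers and skew, the standard monotonic-trend estimator for
#' ecological time series.
#'
#' @param y numeric series.
#' @param t time coordinates (defaults to the index).
#' @return slope, or `NA` with fewer than 2 finite points.
#' @export
theil_sen <- function(y, t = seq_along(y)) {
  keep <- is.finite(y) & is.finite(t)
  y <- y[keep]; t <- t[keep]
  n <- length(y)
  if (n < 2L) return(NA_real_)
  ij <- utils::combn(n, 2L)
  stats::median((y[ij[2L, ]] - y[ij[1L, ]]) / (t[ij[2L, ]] - t[ij[1L, ]]))
}

#' Mann-Kendall trend test (two-sided p)
#'
#' Normal-approximation p-value of the Mann-Kendall S statistic with the
#' tie-corrected variance and continuity correction. Appropriate for
#' serially independent observations (e.g. annual values); for overlapping
#' moving-window series use the surrogate option of [trend_map()] instead,
#' whose calibration does not rely on independence.
#'
#' @param y numeric series, `n >= 4`.
#' @return two-sided p-value in `[0, 1]`, `NA` if fewer than 4 finite values.
#' @export
mann_kendall_p <- function(y) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 4L) return(NA_real_)
  s <- 0
  for (i in seq_len(n - 1L)) s <- s + sum(sign(y[(i + 1L):n] - y[i]))
  tt <- table(y)
  v <- (n * (n - 1) * (2 * n + 5) - sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  if (v <= 0) return(1)
  z <- if (s > 0) (s - 1) / sqrt(v) else if (s < 0) (s + 1) / sqrt(v) else 0
  2 * stats::pnorm(-abs(z))
}

# Mann-Kendall S sign only (for direction checks)
mk_s <- function(y) {
  y <- y[is.finite(y)]
  n <- length(y); s <- 0
  for (i in seq_len(n - 1L)) s <- s + sum(sign(y[(i + 1L):n] - y[i]))
  s
}

# Theil-Sen slopes for every row of a matrix over the column index.
theil_sen_rows <- function(M) {
  nw <- ncol(M)
  ij <- utils::combn(nw, 2L)
  sl <- matrix(NA_real_, nrow(M), ncol(ij))
  for (k in seq_len(ncol(ij)))
    sl[, k] <- (M[, ij[2L, k]] - M[, ij[1L, k]]) / (ij[2L, k] - ij[1L, k])
  apply(sl, 1L, stats::median)
}

mann_kendall_p_rows <- function(M) apply(M, 1L, mann_kendall_p)

#' Per-pixel trend map of a windowed stability metric
#'
#' Theil-Sen slope of the chosen metric's moving-window series, with a
#' significance p-value. Because consecutive 15-year windows share 14
#' years, the window series is strongly autocorrelated and the nominal
#' Mann-Kendall p badly over-rejects under stationarity (~60 percent at
#' alpha = 0.05 in simulation); the default `p_method = "surrogate"`
#' therefore calibrates each pixel against AR(1) surrogate series refit to
#' that pixel's detrended annual record (the standard practice for rolling
#' early-warning indicators). `p_method = "mk"` returns the nominal
#' Mann-Kendall p instead. Slope units: metric change per window step
#' (= per year, windows advance one year at a time).
#'
#' @param ws a [moving_window_metrics()] result.
#' @param metric `"pv"` or `"ar"`.
#' @param p_method `"surrogate"` (default) or `"mk"`.
#' @param n_surrogate surrogate replicates per pixel (p resolution
#'   `1 / (n_surrogate + 1)`).
#' @param seed RNG seed for the surrogate draws.
#' @return object of class `trend_map`: matrices `slope`, `p`, integer
#'   `direction` (1 increasing, -1 decreasing, 0 zero/NA), plus metadata.
#' @export
trend_map <- function(ws, metric = c("pv", "ar"),
                      p_method = c("surrogate", "mk"),
                      n_surrogate = 100L, seed = 1L) {
  stopifnot(inherits(ws, "window_series"))
  metric <- match.arg(metric)
  p_method <- match.arg(p_method)
  arr <- ws[[metric]]
  d <- dim(arr)
  if (d[3L] < 3L) stop("need >= 3 windows per pixel")
  M <- t(matrix(aperm(arr, c(3L, 1L, 2L)), nrow = d[3L]))
  ok <- rowSums(!is.finite(M)) == 0L
  slope <- p <- rep(NA_real_, nrow(M))
  if (any(ok)) {
    slope[ok] <- theil_sen_rows(M[ok, , drop = FALSE])
    if (p_method == "mk") {
      p[ok] <- mann_kendall_p_rows(M[ok, , drop = FALSE])
    } else {
      p[ok] <- surrogate_trend_p(ws, metric, which(ok), slope[ok],
                                 n_surrogate, seed)
    }
  }
  direction <- ifelse(!is.finite(slope), 0L, sign(slope))
  pm <- function(v) matrix(v, d[1L], d[2L])
  structure(list(slope = pm(slope), p = pm(p),
                 direction = pm(as.integer(direction)),
                 metric = metric, p_method = p_method, W = ws$W),
            class = "trend_map")
}

# Parametric surrogate null: per pixel, fit mean/AR(1)/sd on the globally
# detrended annual series, simulate n_surrogate stationary series, rerun the
# window-metric + Theil-Sen pipeline on them, and rank |observed slope|.
surrogate_trend_p <- function(ws, metric, rows, obs_slope, n_surrogate, seed) {
  Y <- ws$annual[rows, , drop = FALSE]
  ny <- ncol(Y)
  R <- detrend_rows(Y, restore_mean = FALSE)
  mu <- rowMeans(Y)
  phi <- ar_rows(R)
  phi[!is.finite(phi)] <- 0
  phi <- pmin(pmax(phi, -0.99), 0.99)
  sdv <- sqrt(rowSums((R - rowMeans(R))^2) / (ny - 1L))
  n <- nrow(Y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cnt <- integer(n)
  W <- ws$W
  n_win <- ny - W + 1L
  for (b in seq_len(n_surrogate)) {
    S <- matrix(0, n, ny)
    S[, 1L] <- stats::rnorm(n, 0, sdv)
    isd <- sdv * sqrt(1 - phi^2)
    for (tt in 2:ny) S[, tt] <- phi * S[, tt - 1L] + stats::rnorm(n, 0, isd)
    Ys <- mu + S
    Ys[Ys <= 0] <- .Machine$double.eps  # PV guard; rare for realistic inputs
    Mw <- matrix(NA_real_, n, n_win)
    for (s in seq_len(n_win)) {
      Rw <- detrend_rows(Ys[, s:(s + W - 1L), drop = FALSE])
      Mw[, s] <- if (metric == "pv") pv_rows(Rw) else ar_rows(Rw - rowMeans(Rw))
    }
    sb <- theil_sen_rows(Mw)
    cnt <- cnt + as.integer(abs(sb) >= abs(obs_slope))
  }
  (1 + cnt) / (1 + n_surrogate)
}

#' Trend map of the annual series itself (ecosystem functioning)
#'
#' Theil-Sen slope + Mann-Kendall p of each pixel's annual values (e.g.
#' annual-maximum kNDVI), the "ecosystem functioning" axis of the
#' ecosystem-state typology. Annual values are not overlapping windows, so
#' the nominal Mann-Kendall test is calibrated here.
#'
#' @param stack a [raster_stack()].
#' @return a `trend_map` (slope per year).
#' @export
annual_trend_map <- function(stack) {
  stopifnot(inherits(stack, "raster_stack"))
  Y <- stack_matrix(stack)
  ok <- as.vector(stack$mask)
  slope <- p <- rep(NA_real_, nrow(Y))
  if (any(ok)) {
    slope[ok] <- theil_sen_rows(Y[ok, , drop = FALSE])
    p[ok] <- mann_kendall_p_rows(Y[ok, , drop = FALSE])
  }
  d <- dim(stack$values)
  pm <- function(v) matrix(v, d[1L], d[2L])
  structure(list(slope = pm(slope), p = pm(p),
                 direction = pm(as.integer(ifelse(!is.finite(slope), 0L, sign(slope)))),
                 metric = "annual", p_method = "mk", W = NA_integer_),
            class = "trend_map")
}

#' Composite destabilization index
#'
#' Three steps: (1) pixels whose PV and AR trends disagree in sign are
#' excluded (zero slopes are non-opposing); (2) each retained slope field
#' is normalized by its maximum absolute value over retained pixels;
#' (3) the two normalized values are summed. Positive values flag
#' destabilization hotspots (variability and memory both rising), negative
#' values stabilization coldspots.
#'
#' @param dar `trend_map` of the AR metric.
#' @param dpv `trend_map` of the PV metric.
#' @return object of class `composite_map`: matrix `value` in `[-2, 2]`,
#'   logical `excluded`, integer `label` (1 = hotspot, 2 = coldspot,
#'   3 = neutral zero, 0 = excluded/invalid), and the two normalization
#'   constants.
#' @export
composite_index <- function(dar, dpv) {
  stopifnot(inherits(dar, "trend_map"), inherits(dpv, "trend_map"))
  if (!identical(dim(dar$slope), dim(dpv$slope)))
    stop("trend maps must share a grid")
  a <- dar$slope; v <- dpv$slope
  finite <- is.finite(a) & is.finite(v)
  opposing <- finite & (sign(a) * sign(v) < 0)
  retained <- finite & !opposing
  if (!any(retained))
    warning("all pixels excluded; composite index is empty")
  norm_a <- if (any(retained)) max(abs(a[retained])) else NA_real_
  norm_v <- if (any(retained)) max(abs(v[retained])) else NA_real_
  value <- matrix(NA_real_, nrow(a), ncol(a))
  if (any(retained)) {
    na <- if (norm_a > 0) a[retained] / norm_a else a[retained] * 0
    nv <- if (norm_v > 0) v[retained] / norm_v else v[retained] * 0
    value[retained] <- na + nv
  }
  label <- matrix(0L, nrow(a), ncol(a))
  label[retained & value > 0] <- 1L
  label[retained & value < 0] <- 2L
  label[retained & value == 0] <- 3L
  structure(list(value = value, excluded = opposing,
                 label = label,
                 norm = c(ar = norm_a, pv = norm_v),
                 labels = c(`1` = "hotspot", `2` = "coldspot",
                            `3` = "neutral", `0` = "excluded")),
            class = "composite_map")
}

#' Global Moran's I with permutation test
#'
#' `I = (N / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` on a raster layer with
#' row-standardized contiguity weights; the p-value comes from random
#' permutations of the values over the valid cells (one-sided toward the
#' observed side of the null expectation `-1/(N-1)`).
#'
#' @param layer numeric matrix (`NA` = invalid cell).
#' @param weights `"rook"` (4-neighbor) or `"queen"` (8-neighbor)
#'   contiguity.
#' @param n_perm number of permutations (>= 99 recommended; conventional
#'   default 999).
#' @param seed RNG seed for the permutations.
#' @return list with `I`, `expected`, `p_value`, `n`, `n_perm`.
#' @export
morans_i <- function(layer, weights = c("rook", "queen"), n_perm = 999L,
                     seed = 1L) {
  weights <- match.arg(weights)
  valid <- which(is.finite(layer))
  n <- length(valid)
  if (n < 9L) stop("need >= 9 valid cells")
  x <- layer[valid]
  if (stats::var(x) == 0) stop("constant layer: Moran's I undefined")
  nr <- nrow(layer); nc <- ncol(layer)
  idx <- matrix(NA_integer_, nr, nc)
  idx[valid] <- seq_len(n)
  steps <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (weights == "queen")
    steps <- c(steps, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  rc <- arrayInd(valid, dim(layer))
  ei <- ej <- integer(0)
  for (s in steps) {
    r2 <- rc[, 1L] + s[1L]; c2 <- rc[, 2L] + s[2L]
    okn <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- rep(NA_integer_, n)
    j[okn] <- idx[cbind(r2[okn], c2[okn])]
    has <- !is.na(j)
    ei <- c(ei, which(has)); ej <- c(ej, j[has])
  }
  deg <- tabulate(ei, nbins = n)
  if (any(deg == 0)) stop("isolated valid cells: no neighbors")
  w <- 1 / deg[ei]                     # row-standardized
  W <- sum(w)                          # = n for row-standardized full rows
  istat <- function(z) {
    zc <- z - mean(z)
    (n / W) * sum(w * zc[ei] * zc[ej]) / sum(zc^2)
  }
  I <- istat(x)
  e0 <- -1 / (n - 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    Ip <- istat(sample(x))
    if ((I >= e0 && Ip >= I) || (I < e0 && Ip <= I)) hits <- hits + 1L
  }
  list(I = I, expected = e0, p_value = (1 + hits) / (1 + n_perm),
       n = n, n_perm = n_perm)
}

default_state_table <- function() {
  # EF = sign of significant functioning trend; ES improving = composite < 0
  data.frame(
    ef = c("up", "up", "down", "down"),
    es = c("improving", "degrading", "improving", "degrading"),
    state = c("ideal", "acceptable", "poor", "abysmal"),
    stringsAsFactors = FALSE
  )
}

#' Five-state ecosystem typology
#'
#' Couples ecosystem functioning (EF: the Theil-Sen slope of the annual
#' vegetation index, significant at `alpha`) with ecosystem stability (ES:
#' the sign of the composite destabilization index, negative = improving).
#' Defaults: EF up + ES improving = ideal; EF up + ES degrading =
#' acceptable; EF down + ES improving = poor; EF down + ES degrading =
#' abysmal; everything else (non-significant EF, excluded or zero ES) =
#' unknown. The mapping is configurable through `state_table`.
#'
#' @param ef a `trend_map` of the annual index (see [annual_trend_map()]).
#' @param es a [composite_index()] result.
#' @param alpha EF significance level.
#' @param state_table data.frame with columns `ef` ("up"/"down"),
#'   `es` ("improving"/"degrading"), `state`.
#' @return object of class `state_map`: integer matrix `code`
#'   (1 = ideal, 2 = acceptable, 3 = poor, 4 = abysmal, 5 = unknown) and the
#'   label table.
#' @export
ecosystem_state <- function(ef, es, alpha = 0.05,
                            state_table = default_state_table()) {
  stopifnot(inherits(ef, "trend_map"), inherits(es, "composite_map"))
  if (!identical(dim(ef$slope), dim(es$value)))
    stop("EF and ES grids differ")
  codes <- c(ideal = 1L, acceptable = 2L, poor = 3L, abysmal = 4L,
             unknown = 5L)
  code <- matrix(5L, nrow(ef$slope), ncol(ef$slope))
  sig <- is.finite(ef$p) & ef$p < alpha & is.finite(ef$slope) & ef$slope != 0
  es_ok <- is.finite(es$value) & !es$excluded & es$value != 0
  efdir <- ifelse(ef$slope > 0, "up", "down")
  esdir <- ifelse(es$value < 0, "improving", "degrading")
  for (k in seq_len(nrow(state_table))) {
    hit <- sig & es_ok & efdir == state_table$ef[k] &
      esdir == state_table$es[k]
    code[hit] <- codes[[state_table$state[k]]]
  }
  structure(list(code = code,
                 labels = c(`1` = "ideal", `2` = "acceptable", `3` = "poor",
                            `4` = "abysmal", `5` = "unknown")),
            class = "state_map")
}
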