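# Independent brute-force oracles; deliberately written as plain double
# loops so they share no code path with the package internals they check.

pv_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    s <- s + abs(x[i] - x[j]) / (x[i] + x[j])
  2 / (n * (n - 1)) * s
}

ar_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  num <- 0
  for (t in 1:(n - 1)) num <- num + (x[t] - m) * (x[t + 1] - m)
  den <- 0
  for (t in 1:n) den <- den + (x[t] - m)^2
  num / den
}

theil_sen_oracle <- function(y, t = seq_along(y)) {
  sl <- c()
  n <- length(y)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    sl <- c(sl, (y[j] - y[i]) / (t[j] - t[i]))
  median(sl)
}

# Row-standardized rook Moran's I by explicit double loop over cell pairs.
# (Adjacency = Manhattan distance 1 between cell centers, precomputed so the
# double loop stays affordable at 1000 random instances.)
moran_oracle <- function(layer) {
  cells <- which(is.finite(layer), arr.ind = TRUE)
  n <- nrow(cells)
  x <- layer[cells]
  z <- x - mean(x)
  manh <- abs(outer(cells[, 1], cells[, 1], "-")) +
    abs(outer(cells[, 2], cells[, 2], "-"))
  nb <- manh == 1
  deg <- rowSums(nb)
  num <- 0; W <- 0
  for (i in 1:n) for (j in 1:n) {
    if (nb[i, j]) {
      w <- 1 / deg[i]
      num <- num + w * z[i] * z[j]
      W <- W + w
    }
  }
  (n / W) * num / sum(z^2)
}

# Construct a stability_map object directly from given fields (used to test
# classification independently of the metric computations).
make_stability_map <- function(pv, ar) {
  structure(list(pv = pv, ar = ar,
                 valid = is.finite(pv) & is.finite(ar),
                 degenerate = matrix(FALSE, nrow(pv), ncol(pv))),
            class = "stability_map")
}

# Construct a trend_map with given slope/p fields.
make_trend_map <- function(slope, p = NULL, metric = "pv") {
  if (is.null(p)) p <- matrix(1, nrow(slope), ncol(slope))
  structure(list(slope = slope, p = p,
                 direction = matrix(as.integer(ifelse(is.finite(slope), sign(slope), 0)),
                                    nrow(slope), ncol(slope)),
                 metric = metric, p_method = "mk", W = 15L),
            class = "trend_map")
}

grid5 <- function(n_rows, n_cols, xll = 0, yll = 0, cellsize = 1)
  list(n_rows = n_rows, n_cols = n_cols, xll = xll, yll = yll,
       cellsize = cellsize)
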