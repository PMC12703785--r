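#' Raster time-series stack
#'
#' The package's core container: one variable observed on a fixed grid over a
#' sequence of years. Values are held as a 3-D array indexed
#' `[row, col, year]` (row 1 = top of the map), with a per-pixel validity
#' mask and a simple georeference (lower-left corner + square cell size, as
#' in ESRI ASCII grids).
#'
#' @param values 3-D numeric array `[row, col, year]`, or a matrix for a
#'   single-year stack.
#' @param years integer vector of calendar year labels, one per layer,
#'   strictly increasing after sorting; layers are reordered to ascending
#'   years.
#' @param mask optional logical matrix (`TRUE` = valid pixel). Defaults to
#'   pixels whose series is finite in every year.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize square cell edge length in map units.
#' @return An object of class `raster_stack` with elements `values`,
#'   `years`, `mask`, `xll`, `yll`, `cellsize`.
#' @examples
#' st <- raster_stack(array(runif(2 * 3 * 4), c(2, 3, 4)), years = 2001:2004)
#' dim(st$values)
#' @export
raster_stack <- function(values, years, mask = NULL, xll = 0, yll = 0,
                         cellsize = 30) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3L)
    stop("`values` must be a [row, col, year] array")
  if (length(years) != dim(values)[3L])
    stop("length(years) must equal the number of layers")
  if (anyDuplicated(years)) stop("duplicate year labels")
  ord <- order(years)
  values <- values[, , ord, drop = FALSE]
  years <- as.integer(years[ord])
  if (is.null(mask)) {
    mask <- apply(is.finite(values), c(1L, 2L), all)
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(values)[1:2]))
      stop("mask dimensions must match the grid")
    mask <- mask & apply(is.finite(values), c(1L, 2L), all)
  }
  structure(list(values = values, years = years, mask = mask,
                 xll = xll, yll = yll, cellsize = cellsize),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_stack> %d x %d grid, %d years (%d-%d), %d/%d valid pixels\n",
              d[1], d[2], d[3], min(x$years), max(x$years),
              sum(x$mask), d[1] * d[2]))
  invisible(x)
}

#' Number of years in a stack
#' @param stack a [raster_stack].
#' @return integer count of layers.
#' @export
n_years <- function(stack) length(stack$years)

# Flatten to a pixels x years matrix (row-major pixel order), plus index map.
# Used internally by every per-pixel vectorized computation.
stack_matrix <- function(stack) {
  d <- dim(stack$values)
  m <- matrix(aperm(stack$values, c(3L, 1L, 2L)), nrow = d[3L])
  t(m) # (npix x nyears), pixel order: column-major over (row, col)
}

# Rebuild a [row, col] matrix from a per-pixel vector in stack_matrix order.
pixel_matrix <- function(v, stack) {
  d <- dim(stack$values)
  matrix(v, nrow = d[1L], ncol = d[2L])
}

grid_equal <- function(a, b) {
  identical(dim(a$values)[1:2], dim(b$values)[1:2]) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize)))
}
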