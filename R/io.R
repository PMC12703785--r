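#' Write / read a single raster layer as ESRI ASCII grid
#'
#' Plain-text, georeferenced raster interchange (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header + row-major values, top row
#' first). Used instead of GeoTIFF so the package has no binary format or
#' GDAL dependency.
#'
#' @param layer numeric matrix (row 1 = top), `NA` = NoData.
#' @param path output file.
#' @param xll,yll,cellsize georeference.
#' @param nodata NoData sentinel written to file.
#' @return (write) the path, invisibly; (read) a list with `layer`, `xll`,
#'   `yll`, `cellsize`.
#' @export
write_ascii_grid <- function(layer, path, xll = 0, yll = 0, cellsize = 30,
                             nodata = -9999) {
  stopifnot(is.matrix(layer))
  hdr <- c(paste("ncols", ncol(layer)), paste("nrows", nrow(layer)),
           paste("xllcorner", format(xll, digits = 15)),
           paste("yllcorner", format(yll, digits = 15)),
           paste("cellsize", format(cellsize, digits = 15)),
           paste("NODATA_value", nodata))
  vals <- layer
  vals[!is.finite(vals)] <- nodata
  body <- apply(vals, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2L]), tolower(kv[, 1L]))
  vals <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  m <- do.call(rbind, vals)
  if (!identical(dim(m), c(as.integer(h[["nrows"]]), as.integer(h[["ncols"]]))))
    stop("ASCII grid body does not match its header")
  m[m == h[["nodata_value"]]] <- NA_real_
  list(layer = m, xll = h[["xllcorner"]], yll = h[["yllcorner"]],
       cellsize = h[["cellsize"]])
}

#' Write a raster stack to disk (one ASCII grid per year + JSON sidecar)
#'
#' @param stack a [raster_stack()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return path of the JSON sidecar (the handle [read_stack()] accepts),
#'   invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "stack") {
  stopifnot(inherits(stack, "raster_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(n_years(stack))
  for (k in seq_len(n_years(stack))) {
    f <- file.path(dir, sprintf("%s_%d.asc", prefix, stack$years[k]))
    layer <- stack$values[, , k]
    layer[!stack$mask] <- NA_real_
    write_ascii_grid(layer, f, stack$xll, stack$yll, stack$cellsize)
    files[k] <- basename(f)
  }
  side <- file.path(dir, paste0(prefix, "_years.json"))
  jsonlite::write_json(list(files = files, years = stack$years),
                       side, auto_unbox = FALSE)
  invisible(side)
}

#' Read a raster stack
#'
#' Accepts either the JSON sidecar written by [write_stack()] or a character
#' vector of ASCII-grid files whose names end in `_<year>.asc`. Layers are
#' sorted by year; grids must agree exactly (no silent resampling).
#'
#' @param path sidecar path or vector of layer files.
#' @return a [raster_stack()].
#' @export
read_stack <- function(path) {
  if (length(path) == 1L && grepl("\\.json$", path)) {
    side <- jsonlite::read_json(path, simplifyVector = TRUE)
    files <- file.path(dirname(path), side$files)
    years <- as.integer(side$years)
  } else {
    files <- path
    pos <- regexpr("_(\\d+)\\.asc$", files)
    if (any(pos < 0))
      stop("missing year metadata: layer files must end in _<year>.asc")
    m <- regmatches(files, pos)
    years <- as.integer(gsub("[^0-9]", "", m))
  }
  gr <- lapply(files, read_ascii_grid)
  ref <- gr[[1L]]
  for (g in gr[-1L]) {
    if (!identical(dim(g$layer), dim(ref$layer)) ||
        !isTRUE(all.equal(c(g$xll, g$yll, g$cellsize),
                          c(ref$xll, ref$yll, ref$cellsize))))
      stop("inconsistent grids across layer files")
  }
  vals <- array(NA_real_, c(dim(ref$layer), length(gr)))
  for (k in seq_along(gr)) vals[, , k] <- gr[[k]]$layer
  raster_stack(vals, years = years, xll = ref$xll, yll = ref$yll,
               cellsize = ref$cellsize)
}

#' Long-format CSV export of a stack
#' @param stack a [raster_stack()].
#' @param path output CSV (`pixel_id`, `row`, `col`, `year`, `value`).
#' @return the path, invisibly.
#' @export
write_stack_csv <- function(stack, path) {
  d <- dim(stack$values)
  df <- expand.grid(row = seq_len(d[1L]), col = seq_len(d[2L]),
                    year = stack$years)
  df$pixel_id <- (df$col - 1L) * d[1L] + df$row
  df$value <- as.vector(stack$values)
  write.csv(df[c("pixel_id", "row", "col", "year", "value")], path,
            row.names = FALSE)
  invisible(path)
}

# ---- flat YAML-style key: value config serialization ----

write_flat_config <- function(x, path) {
  fmt <- function(v) {
    if (is.null(v)) "~" else paste(format(v, digits = 15), collapse = ", ")
  }
  writeLines(paste0(names(x), ": ", vapply(x, fmt, "")), path)
  invisible(path)
}

read_flat_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[[1L]])
    val <- trimws(p[[2L]])
    out[[key]] <- if (val == "~") NULL
      else if (!is.na(suppressWarnings(as.numeric(val)))) as.numeric(val)
      else if (val %in% c("true", "false", "TRUE", "FALSE")) as.logical(toupper(val))
      else val
  }
  out
}
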