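#' Minimal planar raster container
#'
#' A `mds_raster` is a matrix of cell values plus a georeference in planar
#' (projected, UTM-like) meters. Rows are indexed from the north-west
#' corner: cell `[1, 1]` is the NW cell, rows increase southwards, columns
#' increase eastwards. All rasters in a [landscape][make_landscape] share
#' the same extent, resolution and alignment.
#'
#' @param values numeric matrix, `nrow = ny`, `ncol = nx`, row 1 = north.
#' @param xmin,ymax west and north edge coordinates (m).
#' @param res cell side (m), square cells.
#' @return an object of class `mds_raster`.
#' @export
mds_raster <- function(values, xmin, ymax, res) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.finite(res) || res <= 0) stop("invalid-config: resolution must be > 0")
  structure(
    list(values = values, xmin = xmin, ymax = ymax, res = res,
         nx = ncol(values), ny = nrow(values)),
    class = "mds_raster"
  )
}

#' @export
print.mds_raster <- function(x, ...) {
  cat(sprintf("mds_raster: %d x %d cells, res %g m, origin NW (%g, %g)\n",
              x$ny, x$nx, x$res, x$xmin, x$ymax))
  cat(sprintf("  values: [%g, %g]\n", min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Cell-center coordinates of a raster
#'
#' @param r an [mds_raster].
#' @return list with vectors `x` (length nx, west to east) and `y`
#'   (length ny, north to south) of cell-center coordinates (m).
#' @export
raster_centers <- function(r) {
  list(
    x = r$xmin + (seq_len(r$nx) - 0.5) * r$res,
    y = r$ymax - (seq_len(r$ny) - 0.5) * r$res
  )
}

#' Row/column index of the cell containing a point
#'
#' Points exactly on an interior cell edge belong to the cell to the
#' east/south (half-open cells); points on the extent boundary are clamped
#' inward so the extent maximum is still addressable.
#'
#' @param r an [mds_raster].
#' @param x,y point coordinates (m), recycled to common length.
#' @return integer matrix with columns `row`, `col`.
#' @export
raster_cell_index <- function(r, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  col <- floor((x - r$xmin) / r$res) + 1L
  row <- floor((r$ymax - y) / r$res) + 1L
  col <- pmin(pmax(col, 1L), r$nx)
  row <- pmin(pmax(row, 1L), r$ny)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Sample raster values at points (nearest-cell)
#'
#' @inheritParams raster_cell_index
#' @return numeric vector of cell values.
#' @export
raster_extract <- function(r, x, y) {
  idx <- raster_cell_index(r, x, y)
  r$values[idx]
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` format: 6 header lines (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) then rows of values from the
#' north. Readable by QGIS/GDAL and by [read_ascii_grid()].
#'
#' @param r an [mds_raster].
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  vals <- r$values
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$nx),
    sprintf("nrows %d", r$ny),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymax - r$ny * r$res),
    sprintf("cellsize %.10g", r$res),
    sprintf("NODATA_value %g", nodata)
  ), con)
  utils::write.table(format(vals, digits = 15, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @return an [mds_raster]; `NODATA` cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(vals) <- NULL
  vals[vals == h[["nodata_value"]]] <- NA_real_
  mds_raster(vals,
             xmin = h[["xllcorner"]],
             ymax = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]],
             res = h[["cellsize"]])
}

#' Distance-to-nearest-point surface
#'
#' Exact Euclidean distance from every cell center to the nearest of a set
#' of planar points.
#'
#' @param template an [mds_raster] supplying the georeference.
#' @param points two-column matrix (x, y) of point coordinates (m).
#' @return an [mds_raster] of distances (m).
#' @export
distance_surface <- function(template, points) {
  points <- as.matrix(points)
  ctr <- raster_centers(template)
  vals <- matrix(Inf, template$ny, template$nx)
  for (k in seq_len(nrow(points))) {
    d2 <- outer((ctr$y - points[k, 2])^2, (ctr$x - points[k, 1])^2, `+`)
    vals <- pmin(vals, d2)
  }
  mds_raster(sqrt(vals), template$xmin, template$ymax, template$res)
}

# Smooth Gaussian random field: white noise low-pass filtered with a
# separable Gaussian kernel, then standardized to mean 0, sd 1.
smooth_field <- function(ny, nx, range_cells = 8) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  half <- max(1L, ceiling(3 * range_cells))
  u <- seq(-half, half)
  k <- exp(-u^2 / (2 * range_cells^2))
  k <- k / sum(k)
  # reflected index for positions beyond [1, n] (handles pads wider than n)
  reflect <- function(pos, n) {
    if (n == 1) return(rep(1L, length(pos)))
    p <- abs(pos - 1) %% (2 * (n - 1))
    as.integer(ifelse(p >= n - 1, 2 * (n - 1) - p, p) + 1)
  }
  pad_filter <- function(m) {
    n <- ncol(m)
    idx <- reflect(seq(1 - half, n + half), n)
    mp <- m[, idx, drop = FALSE]
    out <- t(apply(mp, 1, function(v) stats::filter(v, k, sides = 2)))
    out[, half + seq_len(n), drop = FALSE]
  }
  z <- pad_filter(z)       # smooth along x
  z <- t(pad_filter(t(z))) # smooth along y
  (z - mean(z)) / stats::sd(z)
}
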