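#' Default landscape configuration
#'
#' Defaults emulate a Patagonian ranching landscape of the scale studied in
#' mara surveys: a ~68 x 68 km projected extent (planar meters, UTM-like),
#' 500 m raster cells, ~40 permanently occupied ranch buildings (sheep
#' ranching divides such landscapes into tens of properties, each with a
#' building), and a masked border strip excluding unsurveyed margins.
#'
#' @param ... overrides for any field (unknown names are an error).
#' @return named list of configuration values.
#' @export
landscape_config <- function(...) {
  cfg <- list(
    width_m = 68000, height_m = 68000,
    res_m = 500,
    n_ranches = 40,
    corr_cvndvi_latitude = 0.55, # collinearity of vegetation CV with latitude
    field_range_cells = 10,      # smoothness of the random covariate fields
    border_mask_m = 4000,        # excluded strip along the extent edge
    seed = NULL
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("invalid-config: unknown landscape option(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  if (cfg$res_m <= 0 || cfg$width_m <= 0 || cfg$height_m <= 0)
    stop("invalid-config: extent and resolution must be positive")
  cfg
}

#' Generate a synthetic landscape
#'
#' Builds the covariate surfaces the abundance model uses: exact Euclidean
#' distance to the nearest ranch building (`ranch_dist`, m), projected
#' longitude and latitude (m), NDVI-like smooth random fields (`mean_ndvi`,
#' `cv_ndvi`, unitless), terrain roughness (`cv_altitude`, unitless) and a
#' sheep stocking rate (`sheep_stock`, animals per square km). The
#' `cv_ndvi` surface is constructed with an exact sample Pearson
#' correlation `corr_cvndvi_latitude` with the latitude surface, so the
#' collinearity screen can be exercised at a known strength. A boolean
#' mask excludes a border strip of width `border_mask_m`.
#'
#' @param config list from [landscape_config()].
#' @return object of class `mds_landscape`: list with `covariates` (named
#'   list of [mds_raster]), `ranch_points` (matrix), `mask` ([mds_raster]
#'   of 0/1), `extent` (xmin, xmax, ymin, ymax) and `config`.
#' @export
make_landscape <- function(config = landscape_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- config$res_m
  nx <- as.integer(round(config$width_m / res))
  ny <- as.integer(round(config$height_m / res))
  if (nx < 2 || ny < 2) stop("invalid-config: extent too small for resolution")
  template <- mds_raster(matrix(0, ny, nx), xmin = 0, ymax = ny * res, res = res)
  ctr <- raster_centers(template)

  ranch_points <- cbind(
    x = stats::runif(config$n_ranches, 0, nx * res),
    y = stats::runif(config$n_ranches, 0, ny * res)
  )
  ranch_dist <- distance_surface(template, ranch_points)

  lon <- mds_raster(matrix(ctr$x, ny, nx, byrow = TRUE), 0, ny * res, res)
  lat <- mds_raster(matrix(ctr$y, ny, nx), 0, ny * res, res)

  fr <- config$field_range_cells
  std <- function(v) (v - mean(v)) / stats::sd(v)
  mean_ndvi <- mds_raster(
    pmin(pmax(0.30 + 0.08 * smooth_field(ny, nx, fr), 0), 1), 0, ny * res, res)

  # cv_ndvi: exact target correlation with latitude by residualizing the
  # noise field against the latitude surface before mixing.
  rho <- config$corr_cvndvi_latitude
  lv <- std(as.vector(lat$values))
  noise <- as.vector(smooth_field(ny, nx, fr))
  noise_perp <- std(stats::residuals(stats::lm(noise ~ lv)))
  zc <- rho * lv + sqrt(1 - rho^2) * noise_perp
  cv_ndvi <- mds_raster(matrix(0.25 + 0.07 * zc, ny, nx), 0, ny * res, res)

  cv_altitude <- mds_raster(
    pmax(0.05 + 0.03 * smooth_field(ny, nx, fr), 0), 0, ny * res, res)
  sheep_stock <- mds_raster(
    pmax(100 + 45 * smooth_field(ny, nx, fr), 0), 0, ny * res, res)

  b <- config$border_mask_m
  inx <- ctr$x > b & ctr$x < nx * res - b
  iny <- ctr$y > b & ctr$y < ny * res - b
  mask <- mds_raster(outer(iny, inx, `&`) * 1, 0, ny * res, res)

  structure(list(
    covariates = list(
      ranch_dist = ranch_dist, longitude = lon, latitude = lat,
      mean_ndvi = mean_ndvi, cv_ndvi = cv_ndvi,
      cv_altitude = cv_altitude, sheep_stock = sheep_stock
    ),
    ranch_points = ranch_points,
    mask = mask,
    extent = c(xmin = 0, xmax = nx * res, ymin = 0, ymax = ny * res),
    config = config
  ), class = "mds_landscape")
}

#' @export
print.mds_landscape <- function(x, ...) {
  cat(sprintf("mds_landscape: %.1f x %.1f km, res %g m, %d ranch buildings\n",
              diff(x$extent[c("xmin", "xmax")]) / 1000,
              diff(x$extent[c("ymin", "ymax")]) / 1000,
              x$covariates[[1]]$res, nrow(x$ranch_points)))
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  cat(sprintf("  mask retains %.1f%% of cells\n", 100 * mean(x$mask$values)))
  invisible(x)
}

#' Area of the unmasked landscape (square km)
#' @param landscape an `mds_landscape`.
#' @export
landscape_area_km2 <- function(landscape) {
  sum(landscape$mask$values) * (landscape$mask$res / 1000)^2
}
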