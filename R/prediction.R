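#' Build a masked prediction grid
#'
#' Lays square cells of `cell_area_km2` row-major from the NW corner of
#' the landscape. A cell is included when the mask at its center is
#' positive (cell-center rule; no partial cells). Covariates are sampled
#' at cell centers exactly as for segments.
#'
#' @param landscape an `mds_landscape`.
#' @param cell_area_km2 cell area (default 4).
#' @param mask optional [mds_raster] overriding the landscape mask;
#'   `NULL` disables masking.
#' @param covariates covariate names to attach (default all).
#' @return object of class `mds_grid`: `cells` data frame (`cell_id`,
#'   `x_m`, `y_m`, `area_km2`, `included`, covariates), `cell_side_m`,
#'   `nx`, `ny`; abundance fields are filled by [predict_abundance()].
#' @export
make_grid <- function(landscape, cell_area_km2 = 4, mask = landscape$mask,
                      covariates = names(landscape$covariates)) {
  side <- sqrt(cell_area_km2) * 1000
  W <- unname(diff(landscape$extent[c("xmin", "xmax")]))
  H <- unname(diff(landscape$extent[c("ymin", "ymax")]))
  nx <- floor(W / side + 1e-9); ny <- floor(H / side + 1e-9)
  if (nx < 1 || ny < 1) stop("empty-grid: cell larger than the extent")
  if (abs(nx * side - W) > 1e-6 || abs(ny * side - H) > 1e-6)
    warning("cell side does not divide the extent; trailing margin dropped")
  xs <- landscape$extent[["xmin"]] + (seq_len(nx) - 0.5) * side
  ys <- landscape$extent[["ymax"]] - (seq_len(ny) - 0.5) * side
  cells <- data.frame(
    cell_id = seq_len(nx * ny),
    x_m = rep(xs, times = ny),     # row-major from the NW corner
    y_m = rep(ys, each = nx),
    area_km2 = cell_area_km2
  )
  cells$included <- if (is.null(mask)) TRUE
                    else raster_extract(mask, cells$x_m, cells$y_m) > 0
  if (!any(cells$included)) stop("empty-grid: mask excludes every cell")
  cells <- extract_covariates(cells, landscape, covariates)
  structure(list(cells = cells, cell_side_m = side, nx = nx, ny = ny,
                 cell_area_km2 = cell_area_km2,
                 total_area_km2 = sum(cells$included) * cell_area_km2),
            class = "mds_grid")
}

#' @export
print.mds_grid <- function(x, ...) {
  cat(sprintf("mds_grid: %d x %d cells of %g km^2, %d included (%.0f km^2)\n",
              x$ny, x$nx, x$cell_area_km2, sum(x$cells$included),
              x$total_area_km2))
  if (!is.null(x$total_abundance))
    cat(sprintf("  total abundance %.1f, overall density %.3f / km^2\n",
                x$total_abundance, x$overall_density))
  invisible(x)
}

# linear-predictor matrix of a dsm fit at prediction cells (offset excluded)
dsm_lpmatrix <- function(fit, cells) {
  nd <- as.data.frame(cells)
  nd$.off <- 0
  stats::predict(fit$gam, newdata = nd, type = "lpmatrix")
}

#' Predict abundance on a grid
#'
#' Per included cell, `N_c = A_c * exp(beta0 + sum_k f_k(z_ck))`:
#' detectability is already absorbed by the offset during fitting, so no
#' division by `p_hat` occurs at prediction. Cells whose covariates fall
#' outside the range observed over the fitted segments are flagged
#' `extrapolated` (reported, not blocked); non-finite predictions are
#' excluded with a warning.
#'
#' @param fit an `mds_dsm`.
#' @param grid an `mds_grid` whose cells carry the model covariates.
#' @return the grid with `N_hat`, `density`, `extrapolated` per cell and
#'   `total_abundance`, `total_area_km2`, `overall_density` filled.
#' @export
predict_abundance <- function(fit, grid) {
  missing_cov <- setdiff(fit$covariates, names(grid$cells))
  if (length(missing_cov))
    stop("invalid-config: grid lacks covariate(s): ",
         paste(missing_cov, collapse = ", "))
  cells <- grid$cells
  inc <- which(cells$included)
  X <- dsm_lpmatrix(fit, cells[inc, , drop = FALSE])
  eta <- as.vector(X %*% stats::coef(fit$gam))
  N <- cells$area_km2[inc] * exp(eta)
  bad <- !is.finite(N)
  if (any(bad)) {
    warning(sum(bad), " cell(s) with non-finite prediction excluded")
    cells$included[inc[bad]] <- FALSE
    N[bad] <- NA_real_
  }
  cells$N_hat <- NA_real_
  cells$N_hat[inc] <- N
  cells$density <- cells$N_hat / cells$area_km2
  extrap <- rep(FALSE, nrow(cells))
  for (nm in fit$covariates) {
    rng <- range(fit$segments[[nm]])
    extrap <- extrap | cells[[nm]] < rng[1] | cells[[nm]] > rng[2]
  }
  cells$extrapolated <- extrap
  grid$cells <- cells
  keep <- cells$included & is.finite(cells$N_hat)
  grid$total_abundance <- sum(cells$N_hat[keep])
  grid$total_area_km2 <- sum(cells$area_km2[keep])
  grid$overall_density <- grid$total_abundance / grid$total_area_km2
  grid
}

# cells of an mds_grid reshaped as an mds_raster (excluded cells NA)
grid_as_raster <- function(grid, column) {
  vals <- matrix(NA_real_, grid$ny, grid$nx)
  v <- grid$cells[[column]]
  v[!grid$cells$included] <- NA_real_
  vals[] <- matrix(v, grid$ny, grid$nx, byrow = TRUE)
  mds_raster(vals,
             xmin = min(grid$cells$x_m) - grid$cell_side_m / 2,
             ymax = max(grid$cells$y_m) + grid$cell_side_m / 2,
             res = grid$cell_side_m)
}

#' Write the per-cell density surface
#'
#' Density `N_c / A_c` per included cell, as an ESRI ASCII raster and a
#' per-cell CSV.
#'
#' @param grid a predicted `mds_grid`.
#' @param raster_path,csv_path output paths (either may be `NULL`).
#' @return the density [mds_raster], invisibly.
#' @export
density_map <- function(grid, raster_path = NULL, csv_path = NULL) {
  if (is.null(grid$cells$density)) stop("empty-grid: predictions missing")
  r <- grid_as_raster(grid, "density")
  if (!is.null(raster_path)) write_ascii_grid(r, raster_path)
  if (!is.null(csv_path)) {
    cols <- intersect(c("cell_id", "x_m", "y_m", "area_km2", "N_hat",
                        "density", "extrapolated"), names(grid$cells))
    utils::write.csv(grid$cells[grid$cells$included, cols], csv_path,
                     row.names = FALSE)
  }
  invisible(r)
}
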