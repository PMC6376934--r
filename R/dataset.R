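#' Write a simulated survey dataset to flat files
#'
#' Emits the pipeline's input files — `sightings.csv`, `transects.csv`,
#' one ESRI ASCII raster per covariate, `mask.asc`, `ranch_points.csv` —
#' plus `truth.json` holding the data-generating parameters and the true
#' group/individual totals for recovery tests, and `manifest.csv` listing
#' every emitted file with its SHA-256.
#'
#' @param landscape an `mds_landscape`.
#' @param transects vertex table.
#' @param sightings sightings table.
#' @param out_dir output directory (created if needed).
#' @param pop optional `mds_population` for the ground truth.
#' @return the manifest data frame (`file`, `sha256`), invisibly.
#' @export
write_dataset <- function(landscape, transects, sightings, out_dir, pop = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(sightings, "sightings.csv")
  wcsv(as.data.frame(transects)[c("transect_id", "vertex_index", "x_m", "y_m")],
       "transects.csv")
  wcsv(data.frame(x_m = landscape$ranch_points[, 1],
                  y_m = landscape$ranch_points[, 2]), "ranch_points.csv")
  for (nm in names(landscape$covariates)) {
    p <- file.path(out_dir, paste0(nm, ".asc"))
    write_ascii_grid(landscape$covariates[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "mask.asc")
  write_ascii_grid(landscape$mask, p)
  paths <- c(paths, p)
  if (!is.null(pop)) {
    p <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(
      beta0 = pop$beta0,
      expected_groups = pop$expected_groups,
      true_groups = pop$n_groups,
      true_individuals = pop$n_individuals,
      group_size = pop$dgp$group_size,
      mean_group_density = pop$dgp$mean_group_density,
      effect_covariates = names(pop$dgp$effects)
    ), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  manifest <- data.frame(
    file = basename(paths),
    sha256 = vapply(paths, function(f)
      digest::digest(f, algo = "sha256", file = TRUE), character(1))
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a survey dataset written by [write_dataset()]
#'
#' Reconstructs the landscape (covariate rasters, mask, ranch points),
#' transect and sightings tables. Rasters round-trip losslessly through
#' the ASCII grid format at the written precision.
#'
#' @param dir dataset directory.
#' @return list: `landscape` (an `mds_landscape`), `transects`,
#'   `sightings`, `truth` (list or NULL).
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("filesystem error: no such directory: ", dir)
  sightings <- utils::read.csv(file.path(dir, "sightings.csv"))
  transects <- utils::read.csv(file.path(dir, "transects.csv"))
  class(transects) <- c("mds_transects", "data.frame")
  asc <- setdiff(list.files(dir, pattern = "\\.asc$"), "mask.asc")
  covs <- lapply(file.path(dir, asc), read_ascii_grid)
  names(covs) <- sub("\\.asc$", "", asc)
  mask <- read_ascii_grid(file.path(dir, "mask.asc"))
  rp_path <- file.path(dir, "ranch_points.csv")
  ranch_points <- if (file.exists(rp_path)) {
    rp <- utils::read.csv(rp_path)
    cbind(x = rp$x_m, y = rp$y_m)
  } else NULL
  r <- mask
  landscape <- structure(list(
    covariates = covs, ranch_points = ranch_points, mask = mask,
    extent = c(xmin = r$xmin, xmax = r$xmin + r$nx * r$res,
               ymin = r$ymax - r$ny * r$res, ymax = r$ymax),
    config = NULL
  ), class = "mds_landscape")
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                            simplifyVector = TRUE)
           else NULL
  list(landscape = landscape, transects = transects, sightings = sightings,
       truth = truth)
}
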