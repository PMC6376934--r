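#' Validate and complete a pipeline configuration
#'
#' Fills defaults (10% truncation, three candidate keys, 1.8 km segments,
#' three response families, alpha 0.01 term selection, |r| < 0.7
#' collinearity screen, 4 km^2 prediction cells) and type/range-checks
#' every field. Unknown keys are rejected.
#'
#' @param raw named list of overrides (possibly empty), or a YAML file
#'   path.
#' @return validated configuration list of class `mds_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  defaults <- list(
    input_dir = NULL,
    out_dir = NULL,
    truncation_fraction = 0.10,
    keys = c("half_normal", "hazard_rate", "uniform"),
    shape_threshold = 0.8,
    seg_length_m = 1800,
    families = c("tweedie", "negbin", "quasipoisson"),
    family_choice = NULL,
    alpha = 0.01,
    collinearity_threshold = 0.7,
    covariates = c("ranch_dist", "longitude", "latitude", "mean_ndvi",
                   "cv_ndvi", "cv_altitude", "sheep_stock"),
    covariate_priority = c("ranch_dist", "mean_ndvi", "cv_ndvi",
                           "cv_altitude", "sheep_stock", "longitude",
                           "latitude"),
    basis_dim = 10,
    cell_area_km2 = 4,
    variance_method = "refit",
    max_lag = 10,
    seed = 1L,
    plots = FALSE,
    landscape = list(),    # passed to landscape_config() when simulating
    total_length_km = 1085.4,
    transect_spacing_m = 1000
  )
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  chk <- function(ok, field, msg)
    if (!ok) stop("validation error: field '", field, "' ", msg)
  chk(is.numeric(cfg$truncation_fraction) && cfg$truncation_fraction >= 0 &&
        cfg$truncation_fraction < 1, "truncation_fraction", "must be in [0, 1)")
  chk(all(cfg$keys %in% c("half_normal", "hazard_rate", "uniform")), "keys",
      "must be a subset of half_normal/hazard_rate/uniform")
  chk(cfg$seg_length_m > 0, "seg_length_m", "must be positive")
  chk(all(cfg$families %in% c("tweedie", "negbin", "quasipoisson")),
      "families", "must be a subset of tweedie/negbin/quasipoisson")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1, "alpha",
      "must be in (0, 1)")
  chk(cfg$collinearity_threshold > 0 && cfg$collinearity_threshold <= 1,
      "collinearity_threshold", "must be in (0, 1]")
  chk(cfg$cell_area_km2 > 0, "cell_area_km2", "must be positive")
  chk(cfg$basis_dim >= 3, "basis_dim", "must be >= 3")
  chk(cfg$shape_threshold > 0 && cfg$shape_threshold <= 1, "shape_threshold",
      "must be in (0, 1]")
  chk(cfg$variance_method %in% c("refit", "delta"), "variance_method",
      "must be refit or delta")
  chk(cfg$total_length_km >= 0, "total_length_km", "must be >= 0")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("mds_config", class(cfg))
  cfg
}

# master seed -> named per-stage substreams (all < 2^31)
spawn_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 6L),
                  c("landscape", "population", "transects", "survey",
                    "residuals", "spare"))
}

#' Simulate a complete survey dataset
#'
#' Generates a landscape, population, transect layout and
#' detection-thinned sightings under the configured defaults, and writes
#' them as pipeline input files.
#'
#' @param config an [validate_config()] list; `config$out_dir` (or
#'   `out_dir`) receives the files.
#' @param out_dir overrides `config$input_dir` as the destination.
#' @param dgp optional [density_params()] override.
#' @param det optional [detection_params()] override.
#' @return list with the in-memory objects (`landscape`, `population`,
#'   `transects`, `sightings`, `manifest`).
#' @export
simulate_dataset <- function(config = validate_config(), out_dir = NULL,
                             dgp = density_params(), det = detection_params()) {
  seeds <- spawn_seeds(config$seed)
  lcfg <- do.call(landscape_config,
                  utils::modifyList(list(seed = seeds[["landscape"]]),
                                    config$landscape))
  landscape <- make_landscape(lcfg)
  pop <- simulate_population(landscape, dgp, seed = seeds[["population"]])
  transects <- layout_transects(landscape, config$transect_spacing_m,
                                config$total_length_km,
                                seed = seeds[["transects"]])
  sightings <- simulate_survey(pop, transects, det, seed = seeds[["survey"]])
  dest <- if (!is.null(out_dir)) out_dir else config$input_dir
  manifest <- NULL
  if (!is.null(dest))
    manifest <- write_dataset(landscape, transects, sightings, dest, pop = pop)
  list(landscape = landscape, population = pop, transects = transects,
       sightings = sightings, manifest = manifest, seeds = seeds)
}

#' Run the full analysis pipeline
#'
#' Detection -> segmentation -> collinearity screen -> density surface
#' model (all families, term selection) -> grid prediction -> variance
#' propagation -> residual correlogram -> report. Every intermediate
#' artifact is written to `config$out_dir`; reruns with the same config
#' and inputs are bit-identical because the only stochastic step (the
#' randomized quantile residuals) is seeded.
#'
#' @param config a [validate_config()] list; `input_dir` must hold a
#'   dataset (see [write_dataset()]), or pass `data` directly.
#' @param data optional list as returned by [read_dataset()] /
#'   [simulate_dataset()], bypassing `input_dir`.
#' @return list of stage results (class `mds_pipeline`): `detfit`,
#'   `segments`, `screen`, `comparison`, `fit`, `grid`, `uncertainty`,
#'   `correlogram`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = validate_config(), data = NULL) {
  if (is.null(data)) {
    if (is.null(config$input_dir))
      stop("validation error: field 'input_dir' is required when no data given")
    data <- read_dataset(config$input_dir)
  }
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- spawn_seeds(config$seed)
  emit <- character(0)
  save_json <- function(x, name) {
    if (is.null(out)) return()
    p <- file.path(out, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
    emit <<- c(emit, p)
  }
  save_csv <- function(d, name) {
    if (is.null(out)) return()
    p <- file.path(out, name)
    utils::write.csv(d, p, row.names = FALSE)
    emit <<- c(emit, p)
  }

  # --- detection ------------------------------------------------------
  sightings <- data$sightings
  if (nrow(sightings) == 0) stop("empty-data: no sightings")
  trunc <- truncate_distances(sightings$perp_distance_m,
                              config$truncation_fraction)
  fits <- lapply(config$keys, function(k)
    fit_key_function(trunc$retained, k, trunc$w))
  detfit <- select_detection_model(fits, trunc$retained,
                                   threshold = config$shape_threshold)
  save_json(list(key = detfit$key, params = as.list(detfit$params),
                 w = detfit$w, p_hat = detfit$p_hat, aic = detfit$aic,
                 loglik = detfit$loglik, n_used = detfit$n_used,
                 vcov = detfit$vcov_params,
                 ranking = attr(detfit, "ranking")), "detfit.json")

  # --- segmentation ---------------------------------------------------
  segments <- segment_transects(data$transects, config$seg_length_m)
  segments <- assign_sightings(sightings, segments, data$transects, detfit$w)
  covars <- intersect(config$covariates, names(data$landscape$covariates))
  segments <- extract_covariates(segments, data$landscape, covars)
  save_csv(segments, "segments.csv")
  screen <- screen_collinearity(segments, covars,
                                threshold = config$collinearity_threshold,
                                priority = config$covariate_priority)

  # --- density surface model + prediction + uncertainty ---------------
  grid <- make_grid(data$landscape, config$cell_area_km2,
                    covariates = covars)
  set.seed(seeds[["residuals"]])
  comparison <- compare_families(segments, screen$retained, detfit, grid,
                                 families = config$families,
                                 alpha = config$alpha,
                                 basis_dim = config$basis_dim,
                                 choose = config$family_choice)
  fit <- comparison$fit
  grid <- predict_abundance(fit, grid)
  unc <- propagate_variance(fit, detfit, grid,
                            method = config$variance_method)
  pv <- term_pvalues(fit)
  save_json(list(family = fit$family, covariates = fit$covariates,
                 intercept = fit$intercept,
                 coefficients = stats::coef(fit$gam),
                 smoothing_parameters = fit$gam$sp,
                 edf = fit$edf, p_values = pv,
                 explained_deviance = explained_deviance(fit),
                 scale = fit$scale,
                 removal_log = attr(fit, "removal_log"),
                 comparison = comparison$table,
                 concurvity = concurvity_measures(fit)), "dsmfit.json")
  if (!is.null(out)) {
    density_map(grid, file.path(out, "density.asc"),
                file.path(out, "predictions.csv"))
    emit <- c(emit, file.path(out, c("density.asc", "predictions.csv")))
  }
  save_json(list(overall_se = unc$overall_se, overall_cv = unc$overall_cv,
                 cv_gam = unc$cv_gam, cv_detection = unc$cv_detection,
                 method = unc$method,
                 total_abundance = unc$total_abundance), "uncertainty.json")
  if (!is.null(out)) {
    cv_map(unc, grid, file.path(out, "cv.asc"), file.path(out, "cv.csv"))
    emit <- c(emit, file.path(out, c("cv.asc", "cv.csv")))
  }

  # --- diagnostics + report -------------------------------------------
  corr <- residual_correlogram(fit, max_lag = config$max_lag)
  save_csv(as.data.frame(corr), "correlogram.csv")
  report <- fit_report(detfit, fit, grid, unc, corr, comparison,
                       json_path = if (!is.null(out)) file.path(out, "report.json"),
                       text_path = if (!is.null(out)) file.path(out, "report.md"))
  if (!is.null(out)) {
    emit <- c(emit, file.path(out, c("report.json", "report.md")))
    if (isTRUE(config$plots)) {
      plot_detection(detfit, trunc$retained,
                     file = file.path(out, "detection.png"))
      plot_partial_effects(fit, file = file.path(out, "partial_effects.png"))
      plot(corr, file = file.path(out, "correlogram.png"))
      emit <- c(emit, file.path(out, c("detection.png", "partial_effects.png",
                                       "correlogram.png")))
    }
  }
  manifest <- NULL
  if (!is.null(out)) {
    emit <- unique(emit[file.exists(emit)])
    manifest <- data.frame(
      file = basename(emit),
      sha256 = vapply(emit, function(f)
        digest::digest(f, algo = "sha256", file = TRUE), character(1)))
    utils::write.csv(manifest, file.path(out, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(detfit = detfit, truncation = trunc, segments = segments,
                 screen = screen, comparison = comparison, fit = fit,
                 grid = grid, uncertainty = unc, correlogram = corr,
                 report = report, manifest = manifest, config = config),
            class = "mds_pipeline")
}

#' @export
print.mds_pipeline <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Read a deposited-style per-segment data table
#'
#' Loads an externally prepared segment table (one row per 1.8 km
#' segment: identifiers, effort, count and covariate columns) such as the
#' per-segment data archived alongside published mara surveys, and
#' validates the columns the density surface model needs. Use this to
#' run [fit_dsm()] directly on real segment data without the upstream
#' simulation or detection stages (supply the published `p_hat`/`w`
#' through an explicit offset).
#'
#' @param path CSV file with at least `transect_id`, `seg_index` (or
#'   `segment_id`), `length_m`, `count`, `area_km2` (or computable from
#'   `length_m` and `w_m`), plus covariate columns.
#' @param w_m truncation distance used to derive `area_km2` when absent.
#' @return a segment data frame usable by [fit_dsm()].
#' @export
read_segment_table <- function(path, w_m = NULL) {
  d <- utils::read.csv(path)
  if (!"segment_id" %in% names(d)) d$segment_id <- seq_len(nrow(d))
  need <- c("count", "length_m")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("data-integrity: segment table lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!"area_km2" %in% names(d)) {
    if (is.null(w_m)) stop("data-integrity: no area_km2 and no w_m given")
    d$area_km2 <- 2 * (w_m / 1000) * (d$length_m / 1000)
  }
  if (any(d$area_km2 <= 0)) stop("data-integrity: non-positive segment area")
  if (any(d$count < 0)) stop("data-integrity: negative count")
  d
}
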