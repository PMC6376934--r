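#' Residual correlogram along transects
#'
#' Lag-l correlation of deviance residuals between segments l steps apart
#' on the same transect, pooled over transects; pairs never span transect
#' boundaries. The approximate 95% band is `+/- 2 / sqrt(m_l)` with `m_l`
#' the number of contributing pairs at lag l.
#'
#' @param fit an `mds_dsm` whose segment table carries `transect_id` and
#'   `seg_index`, or a numeric residual vector with `segments` supplied.
#' @param segments optional segment table when `fit` is a residual vector.
#' @param max_lag largest lag in segment steps (default 10); truncated
#'   with a warning if it exceeds the longest transect.
#' @return object of class `mds_correlogram`: data frame with `lag`, `r`,
#'   `n_pairs`, `band` — empty if no transect has two segments.
#' @export
residual_correlogram <- function(fit, segments = NULL, max_lag = 10) {
  if (inherits(fit, "mds_dsm")) {
    res <- stats::residuals(fit$gam, type = "deviance")
    segments <- fit$segments
  } else {
    res <- as.numeric(fit)
    if (is.null(segments)) stop("segments required with raw residuals")
  }
  ord <- order(segments$transect_id, segments$seg_index)
  res <- res[ord]
  tid <- segments$transect_id[ord]
  runs <- split(seq_along(res), tid)
  longest <- max(vapply(runs, length, integer(1)))
  if (max_lag > longest - 1) {
    if (longest > 1)
      warning("max_lag truncated to ", longest - 1,
              " (longest transect has ", longest, " segments)")
    max_lag <- longest - 1
  }
  rows <- list()
  for (l in seq_len(max_lag)) {
    a <- numeric(0); b <- numeric(0)
    for (idx in runs) {
      n <- length(idx)
      if (n > l) {
        a <- c(a, res[idx[seq_len(n - l)]])
        b <- c(b, res[idx[seq_len(n - l) + l]])
      }
    }
    if (length(a) >= 3)
      rows[[l]] <- data.frame(lag = l, r = stats::cor(a, b),
                              n_pairs = length(a), band = 2 / sqrt(length(a)))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(lag = integer(0), r = numeric(0),
                         n_pairs = integer(0), band = numeric(0))
  class(out) <- c("mds_correlogram", "data.frame")
  out
}

#' Plot a correlogram
#'
#' @param x an `mds_correlogram`.
#' @param file optional PNG path.
#' @param ... ignored.
#' @export
plot.mds_correlogram <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(x$lag, x$r, type = "h", ylim = range(c(-x$band, x$band, x$r)),
                 xlab = "lag (segments along transect)", ylab = "correlation",
                 main = "residual correlogram")
  graphics::lines(x$lag, x$band, lty = 2)
  graphics::lines(x$lag, -x$band, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Assemble the full analysis report
#'
#' One structured document covering the whole reporting surface: retained
#' sightings and truncation distance, selected key function, family
#' comparison (family, retained terms, explained deviance, abundance, SE,
#' CV), retained smooths with p-values and effective degrees of freedom,
#' total abundance and overall density, and a correlogram summary.
#' Missing stages produce explicit gaps rather than errors.
#'
#' @param detfit `mds_detfit` or NULL.
#' @param dsmfit `mds_dsm` or NULL.
#' @param prediction predicted `mds_grid` or NULL.
#' @param uncertainty `mds_uncertainty` or NULL.
#' @param correlogram `mds_correlogram` or NULL.
#' @param comparison output of [compare_families()] or NULL.
#' @param json_path,text_path optional output paths.
#' @return the report as a named list (class `mds_report`).
#' @export
fit_report <- function(detfit = NULL, dsmfit = NULL, prediction = NULL,
                       uncertainty = NULL, correlogram = NULL,
                       comparison = NULL, json_path = NULL, text_path = NULL) {
  gaps <- character(0)
  rep <- list()
  if (is.null(detfit)) gaps <- c(gaps, "detection") else {
    rep$detection <- list(
      key = detfit$key, params = as.list(detfit$params),
      truncation_w_m = detfit$w, p_hat = detfit$p_hat,
      n_retained = detfit$n_used, aic = detfit$aic)
  }
  if (is.null(dsmfit)) gaps <- c(gaps, "dsm") else {
    pv <- term_pvalues(dsmfit)
    rep$dsm <- list(
      family = dsmfit$family,
      n_segments = nrow(dsmfit$segments),
      terms = lapply(stats::setNames(dsmfit$covariates, dsmfit$covariates),
                     function(nm) list(edf = unname(dsmfit$edf[nm]),
                                       p_value = unname(pv[nm]))),
      explained_deviance_pct = explained_deviance(dsmfit))
  }
  if (is.null(prediction) || is.null(prediction$total_abundance))
    gaps <- c(gaps, "prediction")
  else rep$prediction <- list(
    total_abundance = prediction$total_abundance,
    total_area_km2 = prediction$total_area_km2,
    overall_density_km2 = prediction$overall_density,
    n_cells = sum(prediction$cells$included))
  if (is.null(uncertainty)) gaps <- c(gaps, "uncertainty")
  else rep$uncertainty <- list(
    overall_se = uncertainty$overall_se, overall_cv = uncertainty$overall_cv,
    cv_gam = uncertainty$cv_gam, cv_detection = uncertainty$cv_detection,
    method = uncertainty$method)
  if (is.null(correlogram)) gaps <- c(gaps, "correlogram")
  else rep$correlogram <- list(
    lags = correlogram$lag, r = correlogram$r,
    n_pairs = correlogram$n_pairs,
    max_abs_r = if (nrow(correlogram)) max(abs(correlogram$r)) else NA)
  if (!is.null(comparison)) rep$family_comparison <- comparison$table
  rep$gaps <- gaps
  class(rep) <- c("mds_report", class(rep))
  if (!is.null(json_path))
    jsonlite::write_json(unclass(rep), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
  if (!is.null(text_path)) writeLines(format_report(rep), text_path)
  rep
}

format_report <- function(rep) {
  ln <- c("# Density surface model report", "")
  if (!is.null(rep$detection)) {
    d <- rep$detection
    ln <- c(ln, sprintf("Detection: %s key, %d sightings retained, w = %.1f m, p_hat = %.3f",
                        d$key, d$n_retained, d$truncation_w_m, d$p_hat))
  }
  if (!is.null(rep$family_comparison)) {
    fc <- rep$family_comparison
    ln <- c(ln, "", "Family comparison (terms | Exp.Dev. | Ab. | SE | CV):")
    for (i in seq_len(nrow(fc)))
      ln <- c(ln, sprintf("  %-13s %s | %.1f%% | %.0f | %.0f | %.2f",
                          fc$family[i], fc$terms[i], fc$explained_deviance[i],
                          fc$abundance[i], fc$se[i], fc$cv[i]))
  }
  if (!is.null(rep$dsm)) {
    ln <- c(ln, "", sprintf("Selected model: %s", rep$dsm$family))
    for (nm in names(rep$dsm$terms))
      ln <- c(ln, sprintf("  s(%s): edf = %.2f, p = %.3g", nm,
                          rep$dsm$terms[[nm]]$edf, rep$dsm$terms[[nm]]$p_value))
    ln <- c(ln, sprintf("  explained deviance = %.1f%%",
                        rep$dsm$explained_deviance_pct))
  }
  if (!is.null(rep$prediction))
    ln <- c(ln, "", sprintf("Abundance: %.0f individuals over %.0f km^2 (%.2f / km^2)",
                            rep$prediction$total_abundance,
                            rep$prediction$total_area_km2,
                            rep$prediction$overall_density_km2))
  if (!is.null(rep$uncertainty))
    ln <- c(ln, sprintf("Uncertainty: SE = %.0f, CV = %.2f (%s propagation)",
                        rep$uncertainty$overall_se, rep$uncertainty$overall_cv,
                        rep$uncertainty$method))
  if (!is.null(rep$correlogram) && length(rep$correlogram$lags))
    ln <- c(ln, sprintf("Residual correlogram: max |r| = %.2f over %d lags",
                        rep$correlogram$max_abs_r, length(rep$correlogram$lags)))
  if (length(rep$gaps))
    ln <- c(ln, "", paste("Missing stages:", paste(rep$gaps, collapse = ", ")))
  ln
}

#' @export
print.mds_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
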