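#' Per-segment offset for the count model
#'
#' The density surface model describes the expected individual count in
#' segment `j` as `E(n_j) = p_hat * A_j * exp(eta_j)`, so the GAM is
#' fitted with offset `log(p_hat * A_j)`, `A_j` in square km. The linear
#' predictor `eta` is then a log density (individuals per square km).
#'
#' @param detfit an `mds_detfit` (supplies `p_hat`).
#' @param segments segment table with `area_km2`.
#' @return numeric offset vector with attribute `units`.
#' @export
build_offset <- function(detfit, segments) {
  p <- detfit$p_hat
  if (!is.finite(p) || p <= 0 || p > 1) stop("data error: p_hat outside (0, 1]")
  if (any(!is.finite(segments$area_km2)) || any(segments$area_km2 <= 0))
    stop("data error: non-positive segment area")
  off <- log(p * segments$area_km2)
  attr(off, "units") <- "log(p_hat * km^2); exp(eta) is individuals / km^2"
  off
}

map_family <- function(family) {
  switch(family,
    tweedie = mgcv::tw(),
    negbin = mgcv::nb(),
    quasipoisson = stats::quasipoisson(),
    stop("invalid-config: unknown family ", family)
  )
}

#' Fit a density surface model to segment counts
#'
#' Penalized-spline GAM for per-segment individual counts with a
#' `log(p_hat * A_j)` offset: cubic regression spline basis per covariate
#' with REML smoothness selection. With `select = TRUE` (default) each
#' term uses the shrinkage variant of the basis, whose penalty also acts
#' on the null space, so a term's effective degrees of freedom can fall
#' below 1 and uninformative covariates are shrunk away. Response
#' families: Tweedie (power profiled by REML on (1, 2)), negative
#' binomial (theta by REML), or quasi-Poisson (scale by Pearson, extended
#' quasi-likelihood REML analog).
#'
#' @param segments segment table with `count`, `area_km2` and covariate
#'   columns.
#' @param covariates covariate names to enter as univariate smooths; may
#'   be empty for an intercept-only model.
#' @param family "tweedie", "negbin" or "quasipoisson".
#' @param detfit an `mds_detfit` supplying `p_hat` for the offset, or
#'   `NULL` with an explicit `offset`.
#' @param offset optional per-segment offset vector overriding `detfit`.
#' @param basis_dim spline basis dimension per term (default 10, >= 3).
#' @param select use the shrinkage (null-space penalized) basis so edf
#'   can fall below 1 (default TRUE).
#' @return object of class `mds_dsm`: the fitted `gam` plus bookkeeping
#'   (`family`, `covariates`, `segments`, `detfit`, per-term `edf`).
#' @export
fit_dsm <- function(segments, covariates, family = "tweedie", detfit = NULL,
                    offset = NULL, basis_dim = 10, select = TRUE) {
  if (basis_dim < 3) stop("invalid-config: basis_dim must be >= 3")
  if (nrow(segments) < 30) stop("empty-data: need >= 30 segments")
  if (is.null(offset)) {
    if (is.null(detfit)) stop("invalid-config: give detfit or offset")
    offset <- build_offset(detfit, segments)
  }
  dat <- as.data.frame(segments)
  dat$.off <- as.numeric(offset)
  bs <- if (select) "cs" else "cr"
  terms <- if (length(covariates))
    paste(sprintf("s(%s, k = %d, bs = \"%s\")", covariates, basis_dim, bs),
          collapse = " + ")
  else "1"
  fml <- stats::as.formula(paste("count ~", terms, "+ offset(.off)"))
  g <- mgcv::gam(fml, family = map_family(family), data = dat,
                 method = "REML")
  if (!g$converged) stop("fit-failure: penalized IRLS did not converge")
  smry <- summary(g)
  edf <- if (length(covariates)) stats::setNames(smry$s.table[, "edf"], covariates)
         else numeric(0)
  structure(list(
    gam = g, family = family, covariates = covariates,
    basis_dim = basis_dim, select = select,
    segments = dat, detfit = detfit,
    edf = edf, intercept = unname(stats::coef(g)[1]),
    deviance_explained = 100 * smry$dev.expl,
    scale = g$sig2
  ), class = "mds_dsm")
}

#' @export
print.mds_dsm <- function(x, ...) {
  cat(sprintf("mds_dsm: %s family, %d segments, offset log(p_hat * A)\n",
              x$family, nrow(x$segments)))
  if (length(x$covariates)) {
    pv <- term_pvalues(x)
    for (nm in x$covariates)
      cat(sprintf("  s(%s): edf = %.2f, p = %.3g\n", nm, x$edf[nm], pv[nm]))
  } else cat("  intercept-only\n")
  cat(sprintf("  explained deviance = %.1f%%\n", x$deviance_explained))
  invisible(x)
}

#' Approximate p-values for smooth terms
#'
#' Wald-type test of each smooth against zero using the rank-edf
#' pseudoinverse of the term's coefficient covariance (the standard GAM
#' approximate test; F reference for quasi families, chi-square
#' otherwise).
#'
#' @param fit an `mds_dsm`.
#' @return named vector of p-values (one per smooth), in `[0, 1]`.
#' @export
term_pvalues <- function(fit) {
  if (!length(fit$covariates)) return(stats::setNames(numeric(0), character(0)))
  st <- summary(fit$gam)$s.table
  stats::setNames(pmin(pmax(st[, "p-value"], 0), 1), fit$covariates)
}

#' Backward term selection at a significance threshold
#'
#' Iteratively removes the smooth with the largest approximate p-value at
#' or above `alpha` and refits, until every remaining term has
#' `p < alpha`. If all terms are removed an intercept-only model is
#' returned with a warning.
#'
#' @param fit an `mds_dsm` fitted with all candidate smooths.
#' @param alpha retention threshold (default 0.01).
#' @return the reduced `mds_dsm`, with a `removal_log` attribute (data
#'   frame: step, removed, p).
#' @export
select_terms <- function(fit, alpha = 0.01) {
  log_df <- data.frame(step = integer(0), removed = character(0), p = numeric(0))
  step <- 0L
  repeat {
    pv <- term_pvalues(fit)
    if (!length(pv) || max(pv) < alpha) break
    worst <- names(pv)[which.max(pv)]
    step <- step + 1L
    log_df <- rbind(log_df, data.frame(step = step, removed = worst,
                                       p = unname(max(pv))))
    remaining <- setdiff(fit$covariates, worst)
    fit <- fit_dsm(fit$segments, remaining, family = fit$family,
                   offset = fit$segments$.off, basis_dim = fit$basis_dim,
                   select = fit$select)
  }
  if (!length(fit$covariates) && nrow(log_df))
    warning("all smooth terms removed; returning intercept-only model")
  attr(fit, "removal_log") <- log_df
  fit
}

#' Concurvity of the smooth terms
#'
#' For each smooth, the proportion of it that could be explained by the
#' span of the other model terms: the `worst`, `observed` and `estimate`
#' indices, all in `[0, 1]` (computed via [mgcv::concurvity()]).
#'
#' @param fit an `mds_dsm` with at least two smooths.
#' @return data frame, rows = worst/observed/estimate, columns = smooths;
#'   empty data frame for models with fewer than two smooths.
#' @export
concurvity_measures <- function(fit) {
  if (length(fit$covariates) < 2) return(data.frame())
  cc <- mgcv::concurvity(fit$gam, full = TRUE)
  cc <- cc[, colnames(cc) != "para", drop = FALSE]
  as.data.frame(pmin(pmax(cc, 0), 1))
}

#' Percentage of deviance explained
#'
#' `100 * (D_null - D_model) / D_null` against the offset-respecting
#' intercept-only null, using the family (quasi-)deviance.
#'
#' @param fit an `mds_dsm`.
#' @return percent, in `[0, 100]` for converged fits.
#' @export
explained_deviance <- function(fit) {
  d0 <- fit$gam$null.deviance
  if (!is.finite(d0) || d0 <= 0) stop("undefined-deviance: null deviance is zero")
  100 * (d0 - fit$gam$deviance) / d0
}

# randomized-quantile residuals (normal scale); quasi-Poisson has no
# distribution so standardized deviance residuals are used instead
quantile_residuals <- function(fit) {
  g <- fit$gam
  y <- g$y
  mu <- stats::fitted(g)
  if (fit$family == "tweedie") {
    p <- g$family$getTheta(TRUE)
    phi <- g$sig2
    Fy <- ptweedie_cpg(y, mu, p, phi)
    Flo <- ifelse(y <= 0, 0, ptweedie_cpg(pmax(y - 1e-9, 0), mu, p, phi))
    u <- stats::runif(length(y), pmin(Flo, Fy), Fy)
  } else if (fit$family == "negbin") {
    th <- g$family$getTheta(TRUE)
    Fy <- stats::pnbinom(y, size = th, mu = mu)
    Flo <- stats::pnbinom(y - 1, size = th, mu = mu)
    u <- stats::runif(length(y), Flo, Fy)
  } else {
    r <- stats::residuals(g, type = "deviance") / sqrt(g$sig2)
    return(r)
  }
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u)
}

# correlation of sorted residuals with standard normal quantiles
qq_correlation <- function(z) {
  stats::cor(sort(z), stats::qnorm(stats::ppoints(length(z))))
}

#' Fit, select and compare the three response families
#'
#' Fits the base model and runs backward term selection under Tweedie,
#' negative-binomial and quasi-Poisson responses; reports per family the
#' retained smooths, explained deviance, total abundance with SE and CV
#' over the prediction grid, and a randomized-quantile-residual QQ
#' correlation. The family with the best QQ correlation is selected
#' unless `choose` overrides it.
#'
#' @param segments segment table with counts, areas and covariates.
#' @param covariates candidate covariate names.
#' @param detfit the selected `mds_detfit`.
#' @param grid a prediction grid from [make_grid()] (with covariates).
#' @param families subset of c("tweedie", "negbin", "quasipoisson").
#' @param alpha term-selection threshold.
#' @param basis_dim spline basis dimension.
#' @param choose optional family name to force the selection.
#' @param seed seed for the randomized residuals.
#' @return list: `table` (one row per successful family), `fits` (named
#'   list of reduced `mds_dsm`), `selected` (family name), `fit` (the
#'   selected `mds_dsm`).
#' @export
compare_families <- function(segments, covariates, detfit, grid,
                             families = c("tweedie", "negbin", "quasipoisson"),
                             alpha = 0.01, basis_dim = 10, choose = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); fits <- list()
  for (fam in families) {
    res <- tryCatch({
      base <- fit_dsm(segments, covariates, family = fam, detfit = detfit,
                      basis_dim = basis_dim)
      red <- select_terms(base, alpha = alpha)
      pr <- predict_abundance(red, grid)
      un <- propagate_variance(red, detfit, pr)
      z <- quantile_residuals(red)
      list(fit = red,
           row = data.frame(
             family = fam,
             terms = paste(sprintf("s(%s)", red$covariates), collapse = " "),
             explained_deviance = explained_deviance(red),
             abundance = pr$total_abundance,
             se = un$overall_se, cv = un$overall_cv,
             qq_correlation = qq_correlation(z),
             mean_resid = mean(z), var_resid = stats::var(z)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("family ", fam, " failed: ", conditionMessage(res))
      next
    }
    fits[[fam]] <- res$fit
    rows[[fam]] <- res$row
  }
  if (!length(fits)) stop("fit-failure: every family failed")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  selected <- if (!is.null(choose)) choose
              else tab$family[which.max(tab$qq_correlation)]
  if (!selected %in% names(fits)) stop("invalid-config: family ", selected,
                                       " not among successful fits")
  list(table = tab, fits = fits, selected = selected, fit = fits[[selected]])
}

#' Partial-effect plots for the retained smooths
#'
#' One panel per smooth: the estimated term with a 95% band and a rug of
#' observed covariate values, on the link (log-density) scale.
#'
#' @param fit an `mds_dsm`.
#' @param file optional PNG path.
#' @export
plot_partial_effects <- function(fit, file = NULL) {
  if (!length(fit$covariates)) return(invisible(NULL))
  if (!is.null(file)) {
    grDevices::png(file, width = 480 * length(fit$covariates), height = 480)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, length(fit$covariates)))
  on.exit(graphics::par(op), add = TRUE)
  mgcv::plot.gam(fit$gam, shade = TRUE, seWithMean = TRUE, rug = TRUE,
                 shift = 0, pages = 0)
  invisible(NULL)
}
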