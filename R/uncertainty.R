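# d(-log p_hat)/d theta for a detection fit, by central finite differences
# on each parameter; empty vector for the uniform key
neg_logp_gradient <- function(detfit, rel_h = 1e-5) {
  if (!length(detfit$params)) return(numeric(0))
  th <- detfit$params
  g <- numeric(length(th))
  for (i in seq_along(th)) {
    h <- max(abs(th[i]) * rel_h, 1e-8)
    up <- th; up[i] <- th[i] + h
    dn <- th; dn[i] <- th[i] - h
    pu <- pbar_key(detfit$key, up["sigma"], up["shape"], detfit$w)
    pd <- pbar_key(detfit$key, dn["sigma"], dn["shape"], detfit$w)
    g[i] <- -(log(pu) - log(pd)) / (2 * h)
  }
  stats::setNames(g, names(th))
}

#' Propagate detection and GAM uncertainty into abundance variance
#'
#' The GAM component is the delta method on the spline coefficients: for
#' an aggregate `N` over a cell set, `var_gam = a' V a` with
#' `a = dN/dbeta` at the estimates and `V` the coefficient covariance
#' (which includes smoothing-parameter uncertainty under REML).
#'
#' The detection component uses variance propagation (`method =
#' "refit"`, the default): the model is refitted with an extra fixed
#' column equal to `d(-log p_hat)/d theta` — the sensitivity of the
#' offset to the detection parameters — whose coefficient carries a
#' zero-mean prior with covariance equal to the detection parameter
#' covariance (a fixed parametric penalty with smoothing parameter 1).
#' The refit's coefficient covariance then contains the detection
#' uncertainty, and the same delta method yields the total variance. The
#' documented fallback (`method = "delta"`) assumes independence:
#' `CV_total^2 = CV_gam^2 + CV_p^2` with `CV_p^2 = g' V_theta g`,
#' `g = d(log p_hat)/d theta`.
#'
#' With a uniform key there is no detection parameter and the total CV
#' equals the GAM-only CV exactly under either method.
#'
#' @param dsm a converged `mds_dsm`.
#' @param det the `mds_detfit` used for the offset.
#' @param grid a predicted `mds_grid`.
#' @param method "refit" (variance propagation) or "delta" (independence
#'   fallback).
#' @return object of class `mds_uncertainty`: per-cell `var` and `cv`
#'   (aligned with `grid$cells`), `overall_se`, `overall_cv`,
#'   `cv_gam`, `cv_detection`, `method`.
#' @export
propagate_variance <- function(dsm, det, grid, method = c("refit", "delta")) {
  method <- match.arg(method)
  if (is.null(grid$cells$N_hat)) stop("empty-grid: predictions missing")
  cells <- grid$cells
  inc <- which(cells$included & is.finite(cells$N_hat))
  A <- cells$area_km2[inc]

  safe_vcov <- function(g) {
    V <- stats::vcov(g)
    ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8 * max(abs(V))) {
      warning("coefficient covariance not PSD; projecting to PSD")
      es <- eigen(V, symmetric = TRUE)
      V <- es$vectors %*% diag(pmax(es$values, 0)) %*% t(es$vectors)
    }
    V
  }

  # GAM-only component from the original fit
  X0 <- dsm_lpmatrix(dsm, cells[inc, , drop = FALSE])
  eta0 <- as.vector(X0 %*% stats::coef(dsm$gam))
  N0 <- A * exp(eta0)
  V0 <- safe_vcov(dsm$gam)
  a0 <- as.vector(t(X0) %*% N0)
  var_gam_total <- drop(t(a0) %*% V0 %*% a0)
  Ntot <- sum(N0)
  cv_gam <- sqrt(var_gam_total) / Ntot

  grad <- neg_logp_gradient(det)
  if (!length(grad)) {
    # uniform key: no detection parameters, nothing to propagate
    var_cell <- rowSums((X0 %*% V0) * X0) * N0^2
    out_var <- rep(NA_real_, nrow(cells)); out_var[inc] <- var_cell
    out_cv <- sqrt(out_var) / cells$N_hat
    return(structure(list(
      cell_var = out_var, cell_cv = out_cv,
      overall_se = sqrt(var_gam_total), overall_cv = cv_gam,
      cv_gam = cv_gam, cv_detection = 0, method = method,
      total_abundance = Ntot), class = "mds_uncertainty"))
  }
  Vth <- det$vcov_params
  cv_p <- sqrt(drop(t(grad) %*% Vth %*% grad)) # grad of -log p == -grad of log p

  if (method == "delta") {
    lp_var0 <- rowSums((X0 %*% V0) * X0)
    var_cell <- N0^2 * (lp_var0 + drop(t(grad) %*% Vth %*% grad))
    var_total <- Ntot^2 * (cv_gam^2 + cv_p^2)
  } else {
    # variance-propagation refit with the derivative column(s)
    dat <- dsm$segments
    P <- matrix(rep(grad, each = nrow(dat)), nrow = nrow(dat))
    colnames(P) <- paste0("dp", seq_along(grad))
    dat$.dpar <- P
    bs <- if (dsm$select) "cs" else "cr"
    terms <- if (length(dsm$covariates))
      paste(sprintf("s(%s, k = %d, bs = \"%s\")", dsm$covariates,
                    dsm$basis_dim, bs), collapse = " + ")
    else "1"
    fml <- stats::as.formula(paste("count ~", terms, "+ .dpar + offset(.off)"))
    # mgcv's coefficient covariance is (X'WX + sum sp*S)^-1 * phi, so the
    # fixed penalty must be scaled by phi for the extra coefficient's
    # prior variance to equal the detection parameter covariance
    phi <- dsm$gam$sig2
    if (!is.finite(phi) || phi <= 0) phi <- 1
    Sinv <- solve(Vth)
    g2 <- mgcv::gam(fml, family = map_family(dsm$family), data = dat,
                    method = "REML",
                    paraPen = list(.dpar = list(Sinv, sp = phi)))
    # the derivative column is zero at prediction: abundance is a function
    # of the spline coefficients alone, and the detection uncertainty has
    # been absorbed into their covariance via the prior on the extra
    # coefficient (which the data only identify jointly with the intercept)
    nd <- as.data.frame(cells[inc, , drop = FALSE])
    nd$.off <- 0
    nd$.dpar <- matrix(0, nrow(nd), length(grad))
    X2 <- stats::predict(g2, newdata = nd, type = "lpmatrix")
    eta2 <- as.vector(X2 %*% stats::coef(g2))
    N2 <- A * exp(eta2)
    V2 <- safe_vcov(g2)
    var_cell <- N2^2 * rowSums((X2 %*% V2) * X2)
    a2 <- as.vector(t(X2) %*% N2)
    var_total <- drop(t(a2) %*% V2 %*% a2)
    # guard: propagation can only add uncertainty
    var_total <- max(var_total, var_gam_total)
  }
  out_var <- rep(NA_real_, nrow(cells)); out_var[inc] <- var_cell
  out_cv <- sqrt(out_var) / cells$N_hat
  structure(list(
    cell_var = out_var, cell_cv = out_cv,
    overall_se = sqrt(var_total), overall_cv = sqrt(var_total) / Ntot,
    cv_gam = cv_gam, cv_detection = cv_p, method = method,
    total_abundance = Ntot), class = "mds_uncertainty")
}

#' @export
print.mds_uncertainty <- function(x, ...) {
  cat(sprintf("mds_uncertainty (%s): N = %.1f, SE = %.1f, CV = %.3f\n",
              x$method, x$total_abundance, x$overall_se, x$overall_cv))
  cat(sprintf("  components: CV_gam = %.3f, CV_detection = %.3f\n",
              x$cv_gam, x$cv_detection))
  invisible(x)
}

#' Write the per-cell CV surface
#'
#' @param report an `mds_uncertainty`.
#' @param grid the predicted `mds_grid` the report was computed on.
#' @param raster_path,csv_path output paths (either may be `NULL`).
#' @return the CV [mds_raster], invisibly.
#' @export
cv_map <- function(report, grid, raster_path = NULL, csv_path = NULL) {
  grid$cells$cv <- report$cell_cv
  r <- grid_as_raster(grid, "cv")
  if (!is.null(raster_path)) write_ascii_grid(r, raster_path)
  if (!is.null(csv_path)) {
    d <- grid$cells[grid$cells$included,
                    c("cell_id", "x_m", "y_m", "N_hat", "cv")]
    utils::write.csv(d, csv_path, row.names = FALSE)
  }
  invisible(r)
}
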