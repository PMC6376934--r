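#' Percentile truncation of perpendicular distances
#'
#' Removes the `ceiling(fraction * n)` largest distances — the standard
#' robustness step of discarding the 5-10% most extreme sightings before
#' fitting a detection function. The truncation distance `w` is the
#' largest retained distance. Observations tied with the cutoff value are
#' removed together (with a message), so the retained count can fall below
#' `n - ceiling(fraction * n)` in the presence of ties.
#'
#' @param distances nonnegative perpendicular distances (m).
#' @param fraction proportion to remove, in `[0, 1)`.
#' @return list: `retained` (distances), `w` (m), `n_removed`, and the
#'   indices retained (`idx`, into the input order).
#' @export
truncate_distances <- function(distances, fraction = 0.10) {
  if (length(distances) == 0) stop("empty-data: no distances to truncate")
  if (any(distances < 0)) stop("invalid-config: negative distances")
  if (fraction < 0 || fraction >= 1) stop("invalid-config: fraction must be in [0,1)")
  n <- length(distances)
  k <- ceiling(fraction * n)
  if (k == 0) {
    return(list(retained = distances, w = max(distances), n_removed = 0L,
                idx = seq_len(n)))
  }
  ord <- order(distances, decreasing = TRUE)
  cutoff <- distances[ord[k]]
  drop <- distances >= cutoff
  if (sum(drop) > k)
    message("truncate_distances: ", sum(drop) - k,
            " additional observation(s) tied with the cutoff removed")
  idx <- which(!drop)
  if (length(idx) == 0) stop("empty-data: truncation removed all observations")
  list(retained = distances[idx], w = max(distances[idx]),
       n_removed = as.integer(sum(drop)), idx = idx)
}

# average detectability p = integral of g over [0, w] / w
# half-normal in closed form via the normal CDF; hazard-rate by quadrature
pbar_key <- function(key, sigma = NULL, shape = NULL, w) {
  switch(key,
    uniform = 1,
    half_normal = sqrt(2 * pi) * sigma * (stats::pnorm(w / sigma) - 0.5) / w,
    hazard_rate = stats::integrate(function(u) g_key(u, "hazard_rate", sigma, shape),
                                   0, w, rel.tol = 1e-10)$value / w,
    stop("unknown key: ", key)
  )
}

#' Fit a detection key function by conditional maximum likelihood
#'
#' Maximizes the conditional likelihood `prod g(y_i) / mu` with
#' `mu = integral of g over [0, w]`, i.e. the distance-sampling likelihood
#' for perpendicular distances truncated at `w`, assuming certain
#' detection on the line (`g(0) = 1`). Keys: half-normal
#' `g(y) = exp(-y^2 / (2 sigma^2))`, hazard-rate
#' `g(y) = 1 - exp(-(y/sigma)^(-b))` and uniform `g = 1`. Parametric keys
#' are optimized on the log-parameter scale; the parameter covariance is
#' the inverse observed information mapped back to the natural scale.
#'
#' @param distances retained perpendicular distances (m), all in `[0, w]`.
#' @param key "half_normal", "hazard_rate" or "uniform".
#' @param w truncation distance (m).
#' @return object of class `mds_detfit`: `key`, `params` (named: `sigma`,
#'   and `shape` for hazard-rate), `w`, `p_hat`, `loglik`, `aic`,
#'   `vcov_params` (natural scale), `n_used`.
#' @export
fit_key_function <- function(distances, key = c("half_normal", "hazard_rate", "uniform"), w) {
  key <- match.arg(key)
  if (!is.finite(w) || w <= 0) stop("invalid-config: w must be positive")
  if (any(distances < 0 | distances > w))
    stop("invalid-config: distances outside [0, w]")
  n <- length(distances)
  if (key != "uniform" && n < 2) stop("empty-data: need >= 2 distances")
  if (key != "uniform" && all(distances == 0))
    stop("degenerate-data: all distances are zero")

  mk <- function(params, loglik, k, vcov) {
    p_hat <- pbar_key(key, params["sigma"], params["shape"], w)
    structure(list(key = key, params = params, w = w, p_hat = p_hat,
                   loglik = loglik, aic = 2 * k - 2 * loglik,
                   vcov_params = vcov, n_used = n),
              class = "mds_detfit")
  }

  if (key == "uniform") {
    ll <- -n * log(w)
    return(mk(c(sigma = NA_real_, shape = NA_real_)[0], ll, 0L,
              matrix(numeric(0), 0, 0)))
  }

  nll <- if (key == "half_normal") {
    function(lpar) {
      s <- exp(lpar[1])
      mu <- s * sqrt(2 * pi) * (stats::pnorm(w / s) - 0.5)
      sum(distances^2) / (2 * s^2) + n * log(mu)
    }
  } else {
    function(lpar) {
      s <- exp(lpar[1]); b <- exp(lpar[2])
      mu <- tryCatch(
        stats::integrate(function(u) g_key(u, "hazard_rate", s, b), 0, w,
                         rel.tol = 1e-9)$value,
        error = function(e) NA_real_)
      if (!is.finite(mu) || mu <= 0) return(1e10)
      -sum(log(pmax(g_key(distances, "hazard_rate", s, b), 1e-300))) + n * log(mu)
    }
  }
  if (key == "half_normal") {
    # 1-D problem: bracketed golden-section search on log(sigma) is robust
    # to the flat likelihood plateau as sigma -> Inf
    opt <- stats::optimize(function(l) nll(l), interval = log(w) + c(-8, 6),
                           tol = 1e-10)
    lpar <- opt$minimum
    nll_min <- opt$objective
    hess <- stats::optimHess(lpar, function(l) nll(l))
  } else {
    start <- c(log(max(stats::median(distances), 1e-3)), log(2))
    fit <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    # Nelder-Mead can report simplex degeneracy (code 10) at the optimum;
    # restart from the incumbent before declaring failure
    tries <- 0
    while (fit$convergence != 0 && tries < 3) {
      fit <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10))
      tries <- tries + 1
    }
    if (fit$convergence != 0)
      stop("fit-failure: optimizer did not converge (code ", fit$convergence,
           ", value ", fit$value, ")")
    lpar <- fit$par
    nll_min <- fit$value
    hess <- stats::optimHess(lpar, nll)
  }
  pars <- exp(lpar)
  names(pars) <- if (key == "half_normal") "sigma" else c("sigma", "shape")
  vcov_log <- tryCatch(solve(hess), error = function(e) {
    warning("singular information matrix; using pseudo-inverse")
    MASS::ginv(hess)
  })
  D <- diag(pars, length(pars))
  vcov <- D %*% vcov_log %*% D
  dimnames(vcov) <- list(names(pars), names(pars))
  mk(pars, -nll_min, length(pars), vcov)
}

#' @export
print.mds_detfit <- function(x, ...) {
  cat(sprintf("mds_detfit: %s key, w = %.1f m, n = %d\n", x$key, x$w, x$n_used))
  if (length(x$params))
    cat("  params:", paste(sprintf("%s = %.3f", names(x$params), x$params),
                           collapse = ", "), "\n")
  cat(sprintf("  p_hat = %.4f, logLik = %.2f, AIC = %.2f\n",
              x$p_hat, x$loglik, x$aic))
  invisible(x)
}

# fitted detection probability at distance y
detfit_g <- function(fit, y) g_key(y, fit$key, fit$params["sigma"], fit$params["shape"])

#' Shape diagnostics for a fitted detection function
#'
#' Quantifies the "shape criterion": a credible detection function has a
#' shoulder — near-certain detection close to the line — rather than a
#' spike at zero distance. The spike index is `g(w/20) / g(0)`; values
#' much below 1 indicate a spiked fit. For the half-normal the index is
#' bounded below by `exp(-w^2 / (800 sigma^2))`, so it can never flag a
#' spike unless `sigma` is small relative to `w`.
#'
#' @param fit an `mds_detfit`.
#' @param distances the retained distances the fit used.
#' @param bin_width histogram bin width (m); default `w / 12`.
#' @param threshold shoulder threshold on the spike index (default 0.8).
#' @return list: `breaks`, `counts`, `expected` (fitted curve scaled to
#'   expected bin counts), `spike_index`, `shoulder` (logical flag),
#'   `threshold`.
#' @export
shape_diagnostics <- function(fit, distances, bin_width = NULL, threshold = 0.8) {
  if (is.null(bin_width)) bin_width <- fit$w / 12
  breaks <- seq(0, fit$w + bin_width * 1e-9, by = bin_width)
  if (breaks[length(breaks)] < fit$w) breaks <- c(breaks, fit$w)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  mu <- fit$p_hat * fit$w
  expected <- length(distances) * detfit_g(fit, h$mids) / mu * diff(breaks)
  spike <- detfit_g(fit, fit$w / 20) / detfit_g(fit, 0)
  list(breaks = breaks, counts = h$counts, mids = h$mids, expected = expected,
       spike_index = unname(spike), shoulder = unname(spike >= threshold),
       threshold = threshold)
}

#' Plot the distance histogram with the fitted detection curve
#'
#' @param fit an `mds_detfit`.
#' @param distances retained distances.
#' @param file optional PNG path; if given the plot is written there.
#' @param ... passed to [shape_diagnostics()].
#' @return the shape diagnostics, invisibly.
#' @export
plot_detection <- function(fit, distances, file = NULL, ...) {
  sd_ <- shape_diagnostics(fit, distances, ...)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  dens_scale <- length(distances) * mean(diff(sd_$breaks)) / (fit$p_hat * fit$w)
  graphics::hist(distances, breaks = sd_$breaks,
                 main = sprintf("%s detection function (w = %.0f m)", fit$key, fit$w),
                 xlab = "perpendicular distance (m)", col = "grey85")
  yy <- seq(0, fit$w, length.out = 200)
  graphics::lines(yy, dens_scale * detfit_g(fit, yy), lwd = 2)
  invisible(sd_)
}

#' Select a detection model by the shape criterion, then AIC
#'
#' Discards candidates without a shoulder (spike index below threshold),
#' then returns the survivor with the lowest AIC. Ties are broken toward
#' fewer parameters, then by a fixed key order (half-normal, hazard-rate,
#' uniform). The full ranking table is attached as attribute `"ranking"`.
#'
#' @param fits list of `mds_detfit` objects fitted to identical data.
#' @param distances the retained distances (for the spike index).
#' @param threshold shoulder threshold (default 0.8).
#' @return the selected `mds_detfit`, with the ranking table attached.
#' @export
select_detection_model <- function(fits, distances, threshold = 0.8) {
  if (length(fits) == 0) stop("empty-data: no candidate fits")
  key_order <- c(half_normal = 1L, hazard_rate = 2L, uniform = 3L)
  tab <- do.call(rbind, lapply(fits, function(f) {
    sdg <- shape_diagnostics(f, distances, threshold = threshold)
    data.frame(key = f$key, n_params = length(f$params), aic = f$aic,
               spike_index = sdg$spike_index, shoulder = sdg$shoulder)
  }))
  surv <- which(tab$shoulder)
  if (length(surv) == 0)
    stop("no-valid-model: every candidate is spiked near zero distance; ",
         "override the shape threshold in the configuration to force a key")
  ord <- surv[order(tab$aic[surv], tab$n_params[surv], key_order[tab$key[surv]])]
  sel <- fits[[ord[1]]]
  tab <- tab[order(!tab$shoulder, tab$aic), ]
  attr(sel, "ranking") <- tab
  sel
}
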