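#' Lay out systematic parallel transects
#'
#' Parallel north-south lines with a random origin, separated by exactly
#' `spacing_m`, spanning the extent height; the last line is shortened so
#' the total surveyed length matches the request exactly. This mirrors a
#' systematic road/track survey design with a minimum 1 km separation
#' between contiguous tracks.
#'
#' @param landscape an `mds_landscape` (supplies the extent).
#' @param spacing_m minimum separation between lines (m), >= 0.
#' @param total_length_km requested total transect length (km).
#' @param seed optional integer seed for the random origin.
#' @return data frame with columns `transect_id`, `vertex_index`, `x_m`,
#'   `y_m` (polyline vertex order), class `mds_transects`.
#' @export
layout_transects <- function(landscape, spacing_m = 1000, total_length_km, seed = NULL) {
  if (spacing_m < 0) stop("invalid-config: spacing must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (total_length_km <= 0) {
    out <- data.frame(transect_id = integer(0), vertex_index = integer(0),
                      x_m = numeric(0), y_m = numeric(0))
    class(out) <- c("mds_transects", "data.frame")
    return(out)
  }
  # lines are placed inside the unmasked study area (the masked border is
  # unsurveyed habitat), so effort samples the area the model predicts over
  bb <- landscape$extent
  if (!is.null(landscape$mask) && any(landscape$mask$values > 0)) {
    ctr <- raster_centers(landscape$mask)
    half <- landscape$mask$res / 2
    rows <- which(rowSums(landscape$mask$values > 0) > 0)
    cols <- which(colSums(landscape$mask$values > 0) > 0)
    bb <- c(xmin = ctr$x[min(cols)] - half, xmax = ctr$x[max(cols)] + half,
            ymin = ctr$y[max(rows)] - half, ymax = ctr$y[min(rows)] + half)
  }
  W <- unname(bb["xmax"] - bb["xmin"])
  H <- unname(bb["ymax"] - bb["ymin"])
  total_m <- total_length_km * 1000
  n_full <- floor(total_m / H)
  rem <- total_m - n_full * H
  n_lines <- n_full + (rem > 1e-9)
  if (n_lines < 1 || (n_lines - 1) * spacing_m > W)
    stop("infeasible-layout: ", n_lines, " lines at spacing ", spacing_m,
         " m exceed extent width ", W, " m")
  # systematic design: lines spread evenly over the full extent width (so
  # the survey samples the whole covariate range), subject to the minimum
  # separation, with a random origin inside the first interval
  spacing_used <- max(spacing_m, if (n_lines > 1) W / n_lines else W)
  span <- (n_lines - 1) * spacing_used
  x0 <- bb[["xmin"]] + stats::runif(1, 0, W - span)
  xs <- x0 + (seq_len(n_lines) - 1) * spacing_used
  lens <- rep(H, n_lines)
  if (rem > 1e-9) lens[n_lines] <- rem
  y0 <- bb[["ymin"]]
  out <- data.frame(
    transect_id = rep(seq_len(n_lines), each = 2L),
    vertex_index = rep(c(1L, 2L), n_lines),
    x_m = rep(xs, each = 2L),
    y_m = as.vector(rbind(y0, y0 + lens))
  )
  class(out) <- c("mds_transects", "data.frame")
  out
}

#' Per-transect polyline lengths
#'
#' @param transects vertex data frame (`transect_id`, `vertex_index`,
#'   `x_m`, `y_m`).
#' @return named numeric vector of lengths (m) in transect order.
#' @export
transect_lengths <- function(transects) {
  sp <- split(transects[order(transects$transect_id, transects$vertex_index), ],
              transects$transect_id[order(transects$transect_id, transects$vertex_index)])
  vapply(sp, function(d) {
    if (nrow(d) < 2) return(0)
    sum(sqrt(diff(d$x_m)^2 + diff(d$y_m)^2))
  }, numeric(1))
}

# Perpendicular distance and along-line projection of points onto one
# polyline. Returns list(dist, along) with exact point-to-segment
# distances; `along` is the arclength of the nearest projection.
project_onto_polyline <- function(px, py, vx, vy) {
  n <- length(px)
  best_d2 <- rep(Inf, n)
  best_along <- rep(NA_real_, n)
  cum <- c(0, cumsum(sqrt(diff(vx)^2 + diff(vy)^2)))
  for (i in seq_len(length(vx) - 1L)) {
    dx <- vx[i + 1] - vx[i]; dy <- vy[i + 1] - vy[i]
    L2 <- dx * dx + dy * dy
    if (L2 == 0) next
    t <- ((px - vx[i]) * dx + (py - vy[i]) * dy) / L2
    t <- pmin(pmax(t, 0), 1)
    qx <- vx[i] + t * dx; qy <- vy[i] + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_along[upd] <- cum[i] + t[upd] * sqrt(L2)
  }
  list(dist = sqrt(best_d2), along = best_along)
}

#' Detection-process parameters for the survey simulator
#'
#' @param key "half_normal", "hazard_rate" or "uniform".
#' @param sigma scale (m). Default 185 m puts the 90th percentile of
#'   detected half-normal distances near 304 m.
#' @param shape hazard-rate shape b (ignored otherwise).
#' @param w_max hard strip half-width (m): groups beyond it are never
#'   recorded.
#' @export
detection_params <- function(key = "half_normal", sigma = 185, shape = 2,
                             w_max = 500) {
  key <- match.arg(key, c("half_normal", "hazard_rate", "uniform"))
  list(key = key, sigma = sigma, shape = shape, w_max = w_max)
}

# detection probability g(y) at perpendicular distance y
g_key <- function(y, key, sigma = NULL, shape = NULL) {
  switch(key,
    half_normal = exp(-y^2 / (2 * sigma^2)),
    hazard_rate = 1 - exp(-(y / sigma)^(-shape)),
    uniform = rep(1, length(y)),
    stop("unknown key: ", key)
  )
}

#' Simulate a line-transect survey of a population
#'
#' Each group within the strip half-width of its nearest transect is
#' detected independently with probability `g(y)` at its exact
#' perpendicular (point-to-segment) distance `y`. Detection is simulated
#' at the group level, independent of group size.
#'
#' @param pop an `mds_population`.
#' @param transects an `mds_transects` vertex table.
#' @param det a [detection_params()] list.
#' @param seed optional integer seed.
#' @return sightings data frame: `transect_id`, `x_m`, `y_m`,
#'   `perp_distance_m`, `group_size`.
#' @export
simulate_survey <- function(pop, transects, det = detection_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(transect_id = integer(0), x_m = numeric(0), y_m = numeric(0),
                      perp_distance_m = numeric(0), group_size = integer(0))
  if (nrow(pop$groups) == 0 || nrow(transects) == 0) return(empty)
  ids <- unique(transects$transect_id)
  px <- pop$groups$x; py <- pop$groups$y
  best <- rep(Inf, length(px)); best_id <- rep(NA_integer_, length(px))
  for (id in ids) {
    v <- transects[transects$transect_id == id, ]
    v <- v[order(v$vertex_index), ]
    pr <- project_onto_polyline(px, py, v$x_m, v$y_m)
    upd <- pr$dist < best
    best[upd] <- pr$dist[upd]
    best_id[upd] <- id
  }
  in_strip <- best <= det$w_max
  p <- g_key(best, det$key, det$sigma, det$shape)
  detected <- in_strip & stats::runif(length(px)) < p
  data.frame(
    transect_id = best_id[detected],
    x_m = px[detected], y_m = py[detected],
    perp_distance_m = best[detected],
    group_size = pop$groups$size[detected]
  )
}

#' Crude survey summaries
#'
#' Encounter rate (sightings per km of transect) and group-size moments,
#' computed before any truncation.
#'
#' @param sightings sightings data frame.
#' @param effort_km total transect length (km); either give this or
#'   `transects`.
#' @param transects optional vertex table from which effort is computed.
#' @return list: `n_sightings`, `n_individuals`, `effort_km`,
#'   `encounter_rate` (per km), `mean_group_size`, `sd_group_size`.
#' @export
survey_summary <- function(sightings, effort_km = NULL, transects = NULL) {
  if (is.null(effort_km)) {
    if (is.null(transects)) stop("give effort_km or transects")
    effort_km <- sum(transect_lengths(transects)) / 1000
  }
  n <- nrow(sightings)
  list(
    n_sightings = n,
    n_individuals = sum(sightings$group_size),
    effort_km = effort_km,
    encounter_rate = n / effort_km,
    mean_group_size = if (n) mean(sightings$group_size) else NA_real_,
    sd_group_size = if (n > 1) stats::sd(sightings$group_size) else NA_real_
  )
}
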