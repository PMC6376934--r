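# shared simulation helpers; fixtures are built in code, nothing on disk

# half-normal perpendicular distances truncated at w, by rejection from a
# uniform availability distribution (the independent sampling route, not
# the package's survey simulator)
sim_hn_distances <- function(n, sigma, w) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(2000, 0, w)
    out <- c(out, cand[stats::runif(2000) < exp(-cand^2 / (2 * sigma^2))])
  }
  out[seq_len(n)]
}

# a small quick landscape for unit tests (20 x 20 km, 500 m cells)
small_landscape <- function(seed = 5, ...) {
  make_landscape(landscape_config(width_m = 20000, height_m = 20000,
                                  border_mask_m = 2000, seed = seed, ...))
}

# Survey-scale fixed design: 603 segments of 1.8 km (18 transects of
# 59.4 km plus one of 16.2 km), covariates from a fixed landscape, plus a
# 4 km^2 prediction grid. Memoized: built once per test run.
survey_scale_design <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ls <- make_landscape(landscape_config(seed = 101))
    xs <- 5000 + (0:18) * 3100
    lens <- c(rep(59400, 18), 16200)
    tr <- data.frame(transect_id = rep(1:19, each = 2),
                     vertex_index = rep(1:2, 19),
                     x_m = rep(xs, each = 2),
                     y_m = as.vector(rbind(4300, 4300 + lens)))
    segs <- segment_transects(tr, 1800)
    w <- 304
    segs$count <- 0
    segs$area_km2 <- 2 * (w / 1000) * (segs$length_m / 1000)
    segs <- extract_covariates(segs, ls, c("ranch_dist", "longitude"))
    grid <- make_grid(ls, 4, covariates = c("ranch_dist", "longitude"))
    cache <<- list(landscape = ls, transects = tr, segments = segs,
                   grid = grid, w = w)
    cache
  }
})

# Tweedie data-generating process on the survey-scale design: two active
# smooth effects (ranch distance, longitude) calibrated to an expected
# 284 counted individuals (~107 sightings of mean size 2.65) at the true
# half-normal detectability
survey_scale_dgp <- function(design, sigma = 185, p_power = 1.4, phi = 5.2,
                            expected_individuals = 284) {
  f_r <- function(d) 2.2 * exp(-d / 2500)
  f_l <- function(x) 1.2 * (x - 34000) / 34000
  p_true <- maradsm:::pbar_key("half_normal", sigma = sigma, w = design$w)
  lp_raw <- f_r(design$segments$ranch_dist) + f_l(design$segments$longitude)
  b0 <- log(expected_individuals /
              (p_true * sum(design$segments$area_km2 * exp(lp_raw))))
  mu <- p_true * design$segments$area_km2 * exp(b0 + lp_raw)
  inc <- design$grid$cells$included
  N_true <- sum(design$grid$cells$area_km2[inc] *
                  exp(b0 + f_r(design$grid$cells$ranch_dist[inc]) +
                        f_l(design$grid$cells$longitude[inc])))
  list(f_r = f_r, f_l = f_l, b0 = b0, mu = mu, p_true = p_true,
       sigma = sigma, p_power = p_power, phi = phi, N_true = N_true)
}

# construct an mds_detfit without fitting (for variance/identity tests)
manual_detfit <- function(key = "uniform", sigma = NA, w = 300,
                          vcov = matrix(numeric(0), 0, 0), n = 100) {
  params <- if (key == "uniform") stats::setNames(numeric(0), character(0))
            else c(sigma = sigma)
  p_hat <- maradsm:::pbar_key(key, sigma = sigma, w = w)
  structure(list(key = key, params = params, w = w, p_hat = p_hat,
                 loglik = NA_real_, aic = NA_real_, vcov_params = vcov,
                 n_used = n), class = "mds_detfit")
}
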