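test_that("grid construction obeys cell arithmetic and masking", {
  # 100 x 100 km, no mask, 4 km^2 cells -> 2,500 cells, 10,000 km^2
  ls <- make_landscape(landscape_config(width_m = 100000, height_m = 100000,
                                        res_m = 1000, border_mask_m = 0,
                                        seed = 141))
  g <- make_grid(ls, 4, mask = NULL)
  expect_equal(nrow(g$cells), 2500)
  expect_true(all(g$cells$included))
  expect_equal(g$total_area_km2, 10000)
  # mask excluding exactly the southern half -> area halves
  half <- ls$mask
  half$values <- matrix(rep(c(1, 0), each = 50 * 100), 100, 100, byrow = FALSE)
  half$values <- matrix(1, 100, 100); half$values[51:100, ] <- 0
  g2 <- make_grid(ls, 4, mask = half)
  expect_equal(g2$total_area_km2, 5000)
  # cell-center covariate sampling matches direct lookup
  set.seed(142)
  for (k in sample(which(g$cells$included), 5)) {
    expect_equal(g$cells$mean_ndvi[k],
                 raster_extract(ls$covariates$mean_ndvi,
                                g$cells$x_m[k], g$cells$y_m[k]))
  }
})

test_that("intercept-only predictions follow the closed form", {
  set.seed(143)
  n <- 100
  segs <- data.frame(area_km2 = 1, count = rpois(n, 0.5))
  det <- manual_detfit("uniform", w = 300)
  f <- fit_dsm(segs, character(0), family = "quasipoisson", detfit = det)
  ls <- small_landscape(seed = 144)
  g <- make_grid(ls, 4)
  g <- predict_abundance(f, g)
  inc <- g$cells$included
  expect_equal(g$cells$N_hat[inc],
               rep(4 * exp(f$intercept), sum(inc)), tolerance = 1e-9)
  # aggregation identities
  expect_equal(g$total_abundance, sum(g$cells$N_hat[inc]), tolerance = 1e-9)
  expect_equal(g$overall_density * g$total_area_km2, g$total_abundance,
               tolerance = 1e-9)
})

test_that("reported overall density follows from abundance over area", {
  # 3,261 individuals over a 3,476 km^2 prediction area -> 0.94 / km^2
  # at two decimals (0.93 when computed on unrounded inputs)
  n_cells <- 869
  g <- structure(list(
    cells = data.frame(cell_id = 1:n_cells, x_m = 0, y_m = 0, area_km2 = 4,
                       included = TRUE, N_hat = rep(3261 / n_cells, n_cells)),
    cell_side_m = 2000, nx = 69, ny = 13, cell_area_km2 = 4,
    total_area_km2 = 4 * n_cells), class = "mds_grid")
  g$total_abundance <- sum(g$cells$N_hat)
  g$overall_density <- g$total_abundance / g$total_area_km2
  expect_equal(g$total_area_km2, 3476)
  expect_equal(round(g$overall_density, 2), 0.94)
  expect_gte(g$overall_density, 0.93)
})

test_that("density map round-trips through raster and CSV", {
  set.seed(145)
  n <- 80
  segs <- data.frame(area_km2 = 1, count = rpois(n, 1))
  det <- manual_detfit("uniform", w = 300)
  f <- fit_dsm(segs, character(0), family = "quasipoisson", detfit = det)
  ls <- small_landscape(seed = 146)
  g <- predict_abundance(f, make_grid(ls, 4))
  rp <- withr::local_tempfile(fileext = ".asc")
  cp <- withr::local_tempfile(fileext = ".csv")
  r <- density_map(g, rp, cp)
  d <- read.csv(cp)
  r2 <- read_ascii_grid(rp)
  expect_equal(sort(d$density), sort(r2$values[!is.na(r2$values)]),
               tolerance = 1e-9)
  expect_equal(min(r2$values, na.rm = TRUE),
               min(g$cells$density[g$cells$included]), tolerance = 1e-9)
  expect_equal(max(r2$values, na.rm = TRUE),
               max(g$cells$density[g$cells$included]), tolerance = 1e-9)
  # constant prediction -> constant raster
  expect_lt(diff(range(r2$values, na.rm = TRUE)), 1e-9)
})

test_that("excluding cells never increases total abundance", {
  set.seed(147)
  segs <- data.frame(area_km2 = 1, count = rpois(120, 1))
  det <- manual_detfit("uniform", w = 300)
  f <- fit_dsm(segs, character(0), family = "quasipoisson", detfit = det)
  ls <- small_landscape(seed = 148)
  g_all <- predict_abundance(f, make_grid(ls, 4, mask = NULL))
  g_masked <- predict_abundance(f, make_grid(ls, 4))
  expect_lte(g_masked$total_abundance, g_all$total_abundance + 1e-12)
})
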