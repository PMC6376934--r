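make_line <- function(id, x, y0, y1) {
  data.frame(transect_id = id, vertex_index = 1:2, x_m = x, y_m = c(y0, y1))
}

test_that("1,085.4 km of transects split into 603 segments of 1.8 km", {
  # 18 lines of 59.4 km (33 segments each) plus one of 16.2 km (9 segments)
  tr <- do.call(rbind, c(
    lapply(1:18, function(i) make_line(i, i * 3000, 0, 59400)),
    list(make_line(19, 19 * 3000, 0, 16200))))
  segs <- segment_transects(tr, 1800)
  expect_equal(nrow(segs), 603)
  expect_equal(sum(segs$length_m) / 1000, 1085.4, tolerance = 1e-9)
  expect_true(all(abs(segs$length_m - 1800) < 1e-9))
})

test_that("segment splitting preserves effort for awkward lengths", {
  # single transect of exactly 1.8 km -> one segment
  s1 <- segment_transects(make_line(1, 0, 0, 1800), 1800)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$length_m, 1800)
  # 5.0 km -> round(5/1.8) = 3 segments of 1666.67 m
  s3 <- segment_transects(make_line(1, 0, 0, 5000), 1800)
  expect_equal(nrow(s3), 3)
  expect_equal(s3$length_m, rep(5000 / 3, 3), tolerance = 1e-9)
  # effort conservation on a random mixed layout
  set.seed(111)
  tr <- do.call(rbind, lapply(1:7, function(i)
    make_line(i, i * 1000, 0, runif(1, 500, 20000))))
  segs <- segment_transects(tr, 1800)
  expect_equal(sum(segs$length_m), sum(transect_lengths(tr)),
               tolerance = 1e-6)
})

test_that("sightings are assigned to segments with count conservation", {
  tr <- make_line(1, 0, 0, 9000)
  segs <- segment_transects(tr, 1800) # 5 segments of 1800
  # no sightings -> all zero
  empty <- data.frame(transect_id = integer(0), x_m = numeric(0),
                      y_m = numeric(0), perp_distance_m = numeric(0),
                      group_size = integer(0))
  s0 <- assign_sightings(empty, segs, tr, w = 300)
  expect_true(all(s0$count == 0))
  expect_equal(s0$area_km2, rep(2 * 0.3 * 1.8, 5), tolerance = 1e-12)
  # one group of 4 at the midpoint of segment 3
  si <- data.frame(transect_id = 1, x_m = 100, y_m = 4500,
                   perp_distance_m = 100, group_size = 4)
  s1 <- assign_sightings(si, segs, tr, w = 300)
  expect_equal(s1$count, c(0, 0, 4, 0, 0))
  # a sighting exactly on the 2nd/3rd boundary goes downstream (seg 3)
  sb <- data.frame(transect_id = 1, x_m = 50, y_m = 3600,
                   perp_distance_m = 50, group_size = 2)
  s2 <- assign_sightings(sb, segs, tr, w = 300)
  expect_equal(s2$count, c(0, 0, 2, 0, 0))
  # beyond w -> excluded; unknown transect -> error
  far <- data.frame(transect_id = 1, x_m = 400, y_m = 500,
                    perp_distance_m = 400, group_size = 3)
  expect_true(all(assign_sightings(far, segs, tr, w = 300)$count == 0))
  bad <- data.frame(transect_id = 99, x_m = 0, y_m = 0,
                    perp_distance_m = 10, group_size = 1)
  expect_error(assign_sightings(bad, segs, tr, w = 300), "data-integrity")
  # conservation under a random batch
  set.seed(112)
  si <- data.frame(transect_id = 1, x_m = runif(40, -200, 200),
                   y_m = runif(40, 0, 9000),
                   perp_distance_m = runif(40, 0, 290),
                   group_size = sample(1:5, 40, TRUE))
  sN <- assign_sightings(si, segs, tr, w = 300)
  expect_equal(sum(sN$count), sum(si$group_size))
})

test_that("covariate extraction agrees with direct raster lookup", {
  ls <- small_landscape(seed = 113)
  tr <- make_line(1, 5000, 2000, 18000)
  segs <- segment_transects(tr, 1800)
  segs <- extract_covariates(segs, ls)
  set.seed(114)
  for (k in sample(nrow(segs), 5)) {
    expect_equal(segs$mean_ndvi[k],
                 raster_extract(ls$covariates$mean_ndvi,
                                segs$x_m[k], segs$y_m[k]))
  }
  # ranch_dist is exact from points, not the raster
  p <- ls$ranch_points
  d_exact <- sqrt((p[, 1] - segs$x_m[1])^2 + (p[, 2] - segs$y_m[1])^2)
  expect_equal(segs$ranch_dist[1], min(d_exact), tolerance = 1e-9)
  # constant raster extracts the constant
  ls$covariates$flat <- mds_raster(matrix(7, ls$mask$ny, ls$mask$nx),
                                   0, ls$mask$ymax, ls$mask$res)
  segs2 <- extract_covariates(segs, ls, "flat")
  expect_true(all(segs2$flat == 7))
  # midpoint outside the extent is an error
  segs_out <- segs; segs_out$x_m[1] <- -100
  expect_error(extract_covariates(segs_out, ls), "outside")
})

test_that("collinearity screen drops by priority at the 0.7 threshold", {
  set.seed(115)
  n <- 200
  lat <- rnorm(n)
  cvn <- 0.8 * lat + sqrt(1 - 0.64) * rnorm(n) # |r| ~ 0.8 with latitude
  tab <- data.frame(cv_ndvi = cvn, latitude = lat, other = rnorm(n))
  sc <- screen_collinearity(tab, c("cv_ndvi", "latitude", "other"),
                            threshold = 0.7,
                            priority = c("cv_ndvi", "other", "latitude"))
  expect_true("cv_ndvi" %in% sc$retained)
  expect_false("latitude" %in% sc$retained)
  expect_equal(sc$dropped$name, "latitude")
  # duplicated covariate: r = 1, duplicate dropped
  tab$dup <- tab$cv_ndvi
  sc2 <- screen_collinearity(tab, c("cv_ndvi", "dup", "other"),
                             priority = c("cv_ndvi", "other", "dup"))
  expect_false("dup" %in% sc2$retained)
  expect_equal(abs(sc2$cor_matrix["cv_ndvi", "dup"]), 1)
  # orthogonalized covariates all survive (Gram-Schmidt against the
  # intercept too, so Pearson correlations are exactly zero)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))
  tab3 <- data.frame(a = q[, 2], b = q[, 3], c = q[, 4])
  sc3 <- screen_collinearity(tab3, c("a", "b", "c"))
  expect_equal(sort(sc3$retained), c("a", "b", "c"))
  off <- sc3$cor_matrix[upper.tri(sc3$cor_matrix)]
  expect_true(all(abs(off) < 1e-12))
  # zero-variance covariate dropped with a warning
  tab3$z <- 1
  expect_warning(sc4 <- screen_collinearity(tab3, c("a", "b", "z")),
                 "zero-variance")
  expect_false("z" %in% sc4$retained)
})

test_that("segmentation is invariant to transect orientation reversal", {
  tr <- make_line(1, 0, 0, 7200)
  rev_tr <- tr; rev_tr$y_m <- c(7200, 0)
  a <- segment_transects(tr, 1800)
  b <- segment_transects(rev_tr, 1800)
  expect_equal(sort(a$y_m), sort(b$y_m), tolerance = 1e-9)
  expect_equal(a$length_m, b$length_m)
})
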