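test_that("offsets encode log(p_hat * area) with unit bookkeeping", {
  det1 <- manual_detfit("uniform", w = 300)
  segs <- data.frame(area_km2 = c(1, 2, 0.5))
  expect_equal(build_offset(det1, segs), log(c(1, 2, 0.5)),
               ignore_attr = TRUE)
  # p = 0.5, A = 2 -> offset log(1) = 0
  det2 <- manual_detfit("half_normal", sigma = 1e8, w = 300)
  det2$p_hat <- 0.5
  expect_equal(build_offset(det2, data.frame(area_km2 = 2)), 0,
               ignore_attr = TRUE)
  # independent arithmetic oracle on random segments
  set.seed(131)
  A <- runif(100, 0.1, 5)
  o <- build_offset(det2, data.frame(area_km2 = A))
  expect_equal(as.numeric(o), log(0.5) + log(A), tolerance = 1e-12)
  expect_error(build_offset(det2, data.frame(area_km2 = c(1, -1))), "area")
})

test_that("intercept-only fit recovers the ratio mean", {
  set.seed(132)
  n <- 200
  segs <- data.frame(area_km2 = runif(n, 0.5, 2))
  segs$count <- rpois(n, 0.8 * segs$area_km2)
  det <- manual_detfit("uniform", w = 300)
  f <- fit_dsm(segs, character(0), family = "quasipoisson", detfit = det)
  est <- exp(f$intercept)
  target <- sum(segs$count) / sum(segs$area_km2)
  se2 <- 2 * sqrt(diag(vcov(f$gam))[1]) * est
  expect_lt(abs(est - target), se2 + 1e-8)
  # GLM mean identity is exact for the canonical-style fit
  expect_equal(sum(fitted(f$gam)), sum(segs$count), tolerance = 1e-6)
})

test_that("a known smooth surface is recovered on 600 segments", {
  d <- survey_scale_design()
  dgp <- survey_scale_dgp(d)
  set.seed(133)
  segs <- d$segments
  segs$count <- mgcv::rTweedie(dgp$mu, dgp$p_power, 2)
  det <- manual_detfit("uniform", w = 304)
  det$p_hat <- dgp$p_true # fixed known detectability
  f <- fit_dsm(segs, c("ranch_dist", "longitude"), family = "tweedie",
               detfit = det)
  lp_true <- dgp$b0 + dgp$f_r(segs$ranch_dist) + dgp$f_l(segs$longitude)
  lp_hat <- as.vector(predict(f$gam, type = "link")) - f$segments$.off
  expect_gt(cor(lp_true, lp_hat), 0.9)
  # fitted-mean conservation: approximate for Tweedie, whose IRLS weights
  # are non-canonical (exact conservation holds for the quasi-Poisson fit)
  expect_lt(abs(sum(fitted(f$gam)) - sum(segs$count)) / sum(segs$count),
            0.03)
})

test_that("pure-noise covariates are shrunk and p-values behave", {
  d <- survey_scale_design()
  dgp <- survey_scale_dgp(d)
  set.seed(134)
  shrunk <- replicate(8, {
    segs <- d$segments
    segs$count <- mgcv::rTweedie(dgp$mu, dgp$p_power, dgp$phi)
    segs$noise <- rnorm(nrow(segs))
    det <- manual_detfit("uniform", w = 304); det$p_hat <- dgp$p_true
    f <- fit_dsm(segs, c("ranch_dist", "longitude", "noise"),
                 family = "tweedie", detfit = det)
    pv <- term_pvalues(f)
    expect_true(all(pv >= 0 & pv <= 1))
    f$edf["noise"]
  })
  expect_gte(mean(shrunk < 0.5), 0.5) # most replicates shrink the noise term
})

test_that("backward selection keeps active terms and drops the noise", {
  d <- survey_scale_design()
  dgp <- survey_scale_dgp(d)
  set.seed(135)
  segs <- d$segments
  segs$count <- mgcv::rTweedie(dgp$mu, dgp$p_power, 2)
  segs$noise1 <- rnorm(nrow(segs)); segs$noise2 <- rnorm(nrow(segs))
  det <- manual_detfit("uniform", w = 304); det$p_hat <- dgp$p_true
  f <- fit_dsm(segs, c("ranch_dist", "longitude", "noise1", "noise2"),
               family = "tweedie", detfit = det)
  red <- select_terms(f, alpha = 0.01)
  expect_true(all(c("ranch_dist", "longitude") %in% red$covariates))
  expect_false(any(c("noise1", "noise2") %in% red$covariates))
  expect_true(all(term_pvalues(red) < 0.01))
  # no candidates -> intercept-only passthrough
  f0 <- fit_dsm(segs, character(0), family = "tweedie", detfit = det)
  expect_length(select_terms(f0)$covariates, 0)
})

test_that("explained deviance is zero for the null and grows with signal", {
  d <- survey_scale_design()
  dgp <- survey_scale_dgp(d)
  set.seed(136)
  segs <- d$segments
  segs$count <- mgcv::rTweedie(dgp$mu, dgp$p_power, 2)
  det <- manual_detfit("uniform", w = 304); det$p_hat <- dgp$p_true
  f0 <- fit_dsm(segs, character(0), family = "tweedie", detfit = det)
  expect_equal(explained_deviance(f0), 0, tolerance = 1e-8)
  f1 <- fit_dsm(segs, "longitude", family = "tweedie", detfit = det)
  f2 <- fit_dsm(segs, c("longitude", "ranch_dist"), family = "tweedie",
                detfit = det)
  expect_gt(explained_deviance(f1), 0)
  expect_gt(explained_deviance(f2), explained_deviance(f1))
})

test_that("concurvity flags duplicated terms and clears orthogonal ones", {
  set.seed(137)
  n <- 300
  segs <- data.frame(area_km2 = 1, x1 = rnorm(n))
  segs$x2 <- segs$x1 # exact duplicate
  segs$count <- rpois(n, exp(0.2 + 0.5 * sin(segs$x1)))
  det <- manual_detfit("uniform", w = 300)
  f <- fit_dsm(segs, c("x1", "x2"), family = "quasipoisson", detfit = det)
  cc <- concurvity_measures(f)
  expect_true(all(cc["worst", ] > 0.99))
  expect_true(all(cc >= 0 & cc <= 1))
  # independent orthogonalized covariates show low concurvity
  q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  segs2 <- data.frame(area_km2 = 1, a = q[, 1], b = q[, 2])
  segs2$count <- rpois(n, 1)
  f2 <- fit_dsm(segs2, c("a", "b"), family = "quasipoisson", detfit = det)
  cc2 <- concurvity_measures(f2)
  expect_true(all(cc2["worst", ] < 0.3))
  # single-term model: empty result
  f3 <- fit_dsm(segs2, "a", family = "quasipoisson", detfit = det)
  expect_equal(nrow(concurvity_measures(f3)), 0)
})

test_that("family comparison recovers a Tweedie generating process", {
  d <- survey_scale_design()
  dgp <- survey_scale_dgp(d)
  set.seed(138)
  hits <- 0; n_rep <- 5
  for (r in 1:n_rep) {
    segs <- d$segments
    segs$count <- mgcv::rTweedie(dgp$mu, dgp$p_power, dgp$phi)
    det <- manual_detfit("uniform", w = 304); det$p_hat <- dgp$p_true
    cmp <- compare_families(segs, c("ranch_dist", "longitude"), det, d$grid,
                            alpha = 0.01, seed = 1000 + r)
    expect_equal(nrow(cmp$table), 3) # all families fitted
    hits <- hits + (cmp$selected == "tweedie")
  }
  expect_gte(hits, 3) # majority of replicates pick the true family
})

test_that("predictions are invariant to affine covariate rescaling", {
  d <- survey_scale_design()
  dgp <- survey_scale_dgp(d)
  set.seed(139)
  segs <- d$segments
  segs$count <- mgcv::rTweedie(dgp$mu, dgp$p_power, 2)
  det <- manual_detfit("uniform", w = 304); det$p_hat <- dgp$p_true
  f1 <- fit_dsm(segs, "longitude", family = "tweedie", detfit = det)
  segs2 <- segs
  segs2$longitude <- (segs2$longitude - 30000) / 10000
  f2 <- fit_dsm(segs2, "longitude", family = "tweedie", detfit = det)
  # identical up to the tolerance of the REML smoothing-parameter search
  expect_gt(cor(fitted(f1$gam), fitted(f2$gam)), 0.999)
  expect_lt(abs(sum(fitted(f1$gam)) - sum(fitted(f2$gam))) /
              sum(fitted(f1$gam)), 0.01)
})
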