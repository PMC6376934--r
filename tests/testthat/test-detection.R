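test_that("percentile truncation removes the most extreme distances", {
  # 119 sightings at 10% -> 107 retained
  set.seed(101)
  d119 <- runif(119, 0, 600)
  tr <- truncate_distances(d119, 0.10)
  expect_equal(length(tr$retained), 107)
  expect_equal(tr$w, max(tr$retained))
  # fraction 0 is the identity
  tr0 <- truncate_distances(d119, 0)
  expect_equal(length(tr0$retained), 119)
  expect_equal(tr0$w, max(d119))
  # sort-and-slice oracle on 1..10 m
  tr10 <- truncate_distances(1:10, 0.10)
  expect_equal(sort(tr10$retained), 1:9)
  expect_equal(tr10$w, 9)
  expect_error(truncate_distances(numeric(0), 0.1), "empty-data")
})

test_that("uniform key has detectability one exactly", {
  f <- fit_key_function(c(10, 50, 200), "uniform", w = 300)
  expect_identical(f$p_hat, 1)
  expect_equal(f$aic, -2 * f$loglik)
})

test_that("half-normal detectability closed form matches quadrature", {
  for (ratio in c(0.1, 0.5, 1, 2, 10)) {
    w <- 304; sigma <- ratio * w
    closed <- maradsm:::pbar_key("half_normal", sigma = sigma, w = w)
    quad <- integrate(function(u) exp(-u^2 / (2 * sigma^2)), 0, w,
                      rel.tol = 1e-12)$value / w
    expect_lt(abs(closed - quad), 1e-8)
  }
})

test_that("half-normal MLE beats a 100-point likelihood grid", {
  set.seed(102)
  y <- sim_hn_distances(300, 120, 304)
  f <- fit_key_function(y, "half_normal", 304)
  condll <- function(s) {
    mu <- s * sqrt(2 * pi) * (pnorm(304 / s) - 0.5)
    sum(-y^2 / (2 * s^2)) - length(y) * log(mu)
  }
  grid <- seq(30, 1000, length.out = 100)
  expect_gte(f$loglik + 1e-6, max(vapply(grid, condll, numeric(1))))
  expect_equal(f$loglik, condll(f$params["sigma"]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("sigma is recovered without material bias at n = 2000", {
  set.seed(103)
  sig_hat <- replicate(25, {
    y <- sim_hn_distances(2000, 100, 304)
    fit_key_function(y, "half_normal", 304)$params["sigma"]
  })
  expect_lt(abs(mean(sig_hat) - 100) / 100, 0.03)
  # Wald interval coverage is near nominal
  set.seed(104)
  cover <- replicate(40, {
    y <- sim_hn_distances(2000, 100, 304)
    f <- fit_key_function(y, "half_normal", 304)
    se <- sqrt(f$vcov_params["sigma", "sigma"])
    abs(f$params["sigma"] - 100) < 1.96 * se
  })
  expect_gte(mean(cover), 0.85)
})

test_that("detectability is nonincreasing in the truncation distance", {
  p <- vapply(seq(50, 1000, by = 50), function(w)
    maradsm:::pbar_key("half_normal", sigma = 150, w = w), numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("shape diagnostics quantify the shoulder criterion", {
  set.seed(105)
  y <- sim_hn_distances(150, 400, 300)
  # half-normal with sigma >= w: spike index above the closed-form bound
  f <- fit_key_function(y, "half_normal", 300)
  sd_ <- shape_diagnostics(f, y)
  expect_gte(sd_$spike_index, exp(-1 / 800) - 1e-6)
  expect_true(sd_$shoulder)
  # uniform key: spike index exactly 1
  fu <- fit_key_function(y, "uniform", 300)
  expect_identical(shape_diagnostics(fu, y)$spike_index, 1)
  # spiked hazard-rate (b <= 1) fails the shoulder flag
  fh <- fit_key_function(y, "hazard_rate", 300)
  fh$params["shape"] <- 0.7
  fh$params["sigma"] <- 5
  sdh <- shape_diagnostics(fh, y)
  expect_lt(sdh$spike_index, 0.8)
  expect_false(sdh$shoulder)
})

test_that("model selection follows the shape criterion then AIC", {
  set.seed(106)
  y <- sim_hn_distances(200, 150, 304)
  hn <- fit_key_function(y, "half_normal", 304)
  hr <- fit_key_function(y, "hazard_rate", 304)
  un <- fit_key_function(y, "uniform", 304)
  # force the hazard-rate into a spiked shape
  hr$params["shape"] <- 0.5
  hr$params["sigma"] <- 5
  hr$aic <- hn$aic - 10  # would win on AIC were it not spiked
  sel <- select_detection_model(list(hn, hr, un), y)
  expect_equal(sel$key, "half_normal")
  rank <- attr(sel, "ranking")
  expect_equal(nrow(rank), 3)
  expect_false(rank$shoulder[rank$key == "hazard_rate"])
  # ties: equal AIC prefers fewer parameters, then the fixed key order
  un2 <- un; un2$aic <- hn$aic
  sel2 <- select_detection_model(list(hn, un2), y)
  expect_equal(sel2$key, "uniform")  # 0 parameters beats 1 at equal AIC
  hn2 <- hn
  sel3 <- select_detection_model(list(hn, hn2), y)
  expect_equal(sel3$key, "half_normal")
  # all spiked -> explicit error
  expect_error(select_detection_model(list(hr), y), "no-valid-model")
})

test_that("degenerate detection inputs raise explicit errors", {
  expect_error(fit_key_function(c(0, 0, 0), "half_normal", 100),
               "degenerate-data")
  expect_error(fit_key_function(c(10, 20), "half_normal", 5),
               "invalid-config")
  expect_error(fit_key_function(numeric(0), "half_normal", 100), "empty-data")
})
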