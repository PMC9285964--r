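make_coarse <- function(values, lats = c(45, 44.5), lons = c(-100, -99.5),
                        days = 1:10, ref_year = 2019) {
  coarse_cube(values, lats, lons,
              as.vector(t(outer(days, c(0, 0.25, 0.5, 0.75), `+`))), ref_year)
}

test_that("daily aggregation averages the four 6-hour values", {
  v <- array(0, c(2, 2, 4))
  v[, , 1] <- 8; v[, , 2] <- 10; v[, , 3] <- 12; v[, , 4] <- 10
  daily <- aggregate_to_daily(make_coarse(v, days = 1))
  expect_true(all(daily$values == 10))

  const <- make_coarse(array(7, c(2, 2, 40)))
  expect_true(all(aggregate_to_daily(const)$values == 7))
})

test_that("daily aggregation matches a per-day loop and drops the trailing partial day", {
  withr::with_seed(81, v <- array(runif(2 * 2 * 40, 0, 20), c(2, 2, 40)))
  cube <- make_coarse(v)
  daily <- aggregate_to_daily(cube)
  for (d in 1:10) {
    expect_equal(daily$values[, , d], apply(v[, , (4 * d - 3):(4 * d)], c(1, 2), mean))
  }
  # trailing partial day (2 of 4 steps) is dropped
  v2 <- array(runif(2 * 2 * 6, 0, 20), c(2, 2, 6))
  cube2 <- coarse_cube(v2, c(45, 44.5), c(-100, -99.5),
                       1 + 0.25 * (0:5), 2019)
  expect_equal(length(aggregate_to_daily(cube2)$days), 1)
})

test_that("interpolation weights honor constants, exact centers and symmetry", {
  field <- matrix(5, 3, 3)
  lats <- c(45, 44, 43); lons <- c(-100, -99, -98)
  expect_equal(interpolate_idw(field, lats, lons, c(44.6, 43.1), c(-99.7, -98.4)),
               c(5, 5))

  field2 <- matrix(c(1:9), 3, 3)
  expect_equal(interpolate_idw(field2, lats, lons, 44, -99), field2[2, 2])

  # midpoint of two equal-distance centers valued 0 and 10
  f <- matrix(c(0, 10), 1, 2)
  expect_equal(interpolate_idw(f, 44, c(-100, -99), 44, -99.5, k = 2), 5)

  # outside the coarse bounding box: nearest neighbor
  expect_equal(interpolate_idw(field2, lats, lons, 47, -101), field2[1, 1])
  expect_error(interpolate_idw(matrix(nrow = 0, ncol = 0), numeric(0), numeric(0), 44, -99),
               "empty")
})

test_that("asynchronous regression recovers exact affine maps under any time permutation", {
  withr::with_seed(82, x <- rnorm(200, 10, 3))
  y <- 1.5 * x - 2
  f <- fit_asynchronous_regression(x, y)
  expect_equal(unname(f["slope"]), 1.5, tolerance = 1e-10)
  expect_equal(unname(f["intercept"]), -2, tolerance = 1e-9)

  perm <- withr::with_seed(83, fit_asynchronous_regression(sample(x), sample(y)))
  expect_equal(f, perm, tolerance = 1e-10)

  ident <- withr::with_seed(84, fit_asynchronous_regression(sample(x), x))
  expect_equal(unname(ident["slope"]), 1, tolerance = 1e-10)
  expect_equal(unname(ident["intercept"]), 0, tolerance = 1e-9)
})

test_that("asynchronous regression estimates a noisy slope by rank pairing", {
  withr::with_seed(85, {
    x <- rnorm(600, 10, 3)
    y <- 0.8 * x + 2 + rnorm(600, 0, 0.5)
  })
  f <- fit_asynchronous_regression(x, y)
  expect_gte(unname(f["slope"]), 0.75)
  expect_lte(unname(f["slope"]), 0.85)
})

test_that("asynchronous regression pairs unequal sample lengths by quantile", {
  withr::with_seed(86, x <- rnorm(400, 10, 3))
  y <- 2 * x + 1
  # drop two-thirds of the fine days: the map comes back up to the
  # sampling noise of comparing a subsample's quantiles with the full set
  f <- fit_asynchronous_regression(x, y[seq(1, 400, by = 3)])
  expect_equal(unname(f["slope"]), 2, tolerance = 0.1)
})

test_that("degenerate regressions are rejected", {
  expect_error(fit_asynchronous_regression(rep(5, 50), rnorm(50)), "zero variance")
  expect_error(fit_asynchronous_regression(rnorm(10), rnorm(10)), "at least 30")
})

test_that("the downscaling model recovers known per-cell monthly maps", {
  fl <- seq(44, 43, length.out = 2); fo <- seq(-98, -97, length.out = 2)
  pair <- synth_coarse_fine_pair(87, fl, fo, years = 2, noise_sd = 0)
  model <- build_downscaling_model(pair$coarse_daily, pair$fine)
  expect_lt(max(abs(model$slope - pair$slope)), 1e-8)
  expect_lt(max(abs(model$intercept - pair$intercept)), 1e-8)
})

test_that("a uniform offset archive yields unit slopes and the offset as intercept", {
  fl <- c(44, 43.5); fo <- c(-98, -97.5)
  pair <- synth_coarse_fine_pair(88, fl, fo, years = 2,
                                 slope_range = c(1, 1), intercept_range = c(1, 1))
  model <- build_downscaling_model(pair$coarse_daily, pair$fine)
  expect_equal(as.vector(model$slope), rep(1, length(model$slope)), tolerance = 1e-8)
  expect_equal(as.vector(model$intercept), rep(1, length(model$intercept)), tolerance = 1e-7)
})

test_that("zero-variance cell-months are flagged missing, not fabricated", {
  lats <- c(44, 43.5); lons <- c(-98, -97.5)
  n_days <- 730
  const_coarse <- temperature_cube(array(10, c(2, 2, n_days)), lats, lons,
                                   seq_len(n_days), 2015)
  fine <- temperature_cube(array(12, c(2, 2, n_days)), lats, lons,
                           seq_len(n_days), 2015)
  model <- build_downscaling_model(const_coarse, fine)
  expect_true(all(is.na(model$slope)))
})

test_that("applying the model performs the per-month affine map after regridding", {
  fl <- c(44, 43.5); fo <- c(-98, -97.5)
  pair <- synth_coarse_fine_pair(89, fl, fo, years = 2, noise_sd = 0)
  model <- build_downscaling_model(pair$coarse_daily, pair$fine)
  ds <- apply_downscaling(pair$coarse, model)
  expect_lt(max(abs(ds$values - pair$fine_true$values)), 1e-7)

  # identity maps: output equals the regridded daily means
  ident <- model
  ident$slope[] <- 1; ident$intercept[] <- 0
  regrid <- apply_downscaling(pair$coarse, ident)
  manual <- sapply(seq_along(pair$coarse_daily$days), function(d) {
    interpolate_idw(pair$coarse_daily$values[, , d], pair$coarse_daily$lats,
                    pair$coarse_daily$lons,
                    rep(fl, times = 2), rep(fo, each = 2))
  })
  expect_equal(matrix(regrid$values, 4, length(pair$coarse_daily$days)), manual,
               tolerance = 1e-10)
})

test_that("downscaled output is monotone in the coarse input where slopes are positive", {
  fl <- c(44, 43.5); fo <- c(-98, -97.5)
  pair <- synth_coarse_fine_pair(90, fl, fo, years = 2, noise_sd = 0,
                                 slope_range = c(0.5, 1.5))
  model <- build_downscaling_model(pair$coarse_daily, pair$fine)
  warm <- pair$coarse
  warm$values <- warm$values + 1
  base_out <- apply_downscaling(pair$coarse, model)
  warm_out <- apply_downscaling(warm, model)
  expect_true(all(warm_out$values >= base_out$values))
})

test_that("round-trip downscaling error stays small under observation noise", {
  fl <- seq(44, 43, length.out = 3); fo <- seq(-98, -97, length.out = 3)
  pair <- synth_coarse_fine_pair(91, fl, fo, years = 2, noise_sd = 0.5)
  model <- build_downscaling_model(pair$coarse_daily, pair$fine)
  ds <- apply_downscaling(pair$coarse, model)
  expect_lt(mean(abs(ds$values - pair$fine_true$values)), 0.2)
})
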