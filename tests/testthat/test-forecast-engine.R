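mini_cube <- function(days, temp = 10, nlat = 2, nlon = 2, ref_year = 2019) {
  temperature_cube(array(temp, c(nlat, nlon, length(days))),
                   seq(45, 44, length.out = nlat), seq(-100, -99, length.out = nlon),
                   days, ref_year)
}

test_that("observed and forecast cubes splice exactly at the issue day", {
  m <- assemble_member(mini_cube(-60:100), mini_cube(101:270, temp = 12), issue_day = 101)
  expect_equal(m$cube$days, -60:270)
  expect_equal(unique(m$provenance[m$cube$days < 101]), "observed")
  expect_equal(unique(m$provenance[m$cube$days >= 101]), "forecast")
  expect_true(all(m$cube$values[, , m$cube$days >= 101] == 12))
})

test_that("a coverage gap at the splice is reported with the missing day", {
  expect_error(
    assemble_member(mini_cube(-60:100), mini_cube(102:270), issue_day = 102),
    "101"
  )
})

test_that("forecast values win on overlap days", {
  m <- assemble_member(mini_cube(-60:103, temp = 10), mini_cube(101:270, temp = 15),
                       issue_day = 101)
  expect_equal(m$cube$days, -60:270)
  overlap <- m$cube$days %in% 101:103
  expect_true(all(m$cube$values[, , overlap] == 15))
  expect_true(all(m$cube$values[, , m$cube$days == 100] == 10))
})

test_that("member forecasts equal a per-member oracle and respect warming", {
  ens <- structure(
    list(members = list(tt = tt_model(T_base = 0, F_star = 400)),
         weights = c(tt = 1), cv = NULL),
    class = "stacked_ensemble"
  )
  cubes <- lapply(c(0, 0, 5), function(dt) {
    cube <- synth_temperature_cube(61, nlat = 4, nlon = 4, noise_sd = 1)
    cube$values <- cube$values + dt
    cube
  })
  grids <- run_member_forecasts(cubes, ens)
  expect_equal(grids[[1]], grids[[2]])
  expect_true(all(grids[[3]] <= grids[[1]], na.rm = TRUE))
  oracle <- predict_ensemble(cubes[[3]], ens)
  expect_equal(grids[[3]], oracle)
  expect_error(run_member_forecasts(list(), ens), "at least one")
})

test_that("member summary reproduces the sample statistics", {
  grids <- lapply(c(90, 95, 100, 105, 110), function(v) matrix(as.integer(v), 2, 2))
  s <- summarize_members(grids)
  expect_true(all(s$point_estimate == 100))
  expect_equal(s$sd[1, 1], sd(c(90, 95, 100, 105, 110)))
  expect_equal(s$sd[1, 1], 7.905694, tolerance = 1e-6)
  expect_equal(s$pi_low[1, 1], 100 - 1.96 * s$sd[1, 1])
  expect_equal(s$pi_high[1, 1], 100 + 1.96 * s$sd[1, 1])

  same <- summarize_members(lapply(1:5, function(i) matrix(100L, 2, 2)))
  expect_true(all(same$sd == 0))
  expect_true(all(same$pi_low == 100 & same$pi_high == 100))
  expect_error(summarize_members(grids[1]), "at least 2")
})

test_that("non-responding members follow the responder-majority rule", {
  g <- lapply(c(100, 100, 100, 100, NA), function(v) matrix(as.integer(v), 2, 2))
  s <- summarize_members(g)
  expect_true(all(s$point_estimate == 100))
  expect_true(all(s$partial))
  expect_equal(s$n_members, 5)

  # only 2 of 5 respond: below the 3-of-5 floor
  g2 <- lapply(c(100, 100, NA, NA, NA), function(v) matrix(as.integer(v), 2, 2))
  s2 <- summarize_members(g2)
  expect_true(all(is.na(s2$point_estimate)))
})

test_that("anomalies are the difference from the latitude baseline", {
  baseline <- structure(list(beta0 = 200, beta1 = -2, n_obs = 10, sigma = 1,
                             se = c(1, 0.1)), class = "latitude_baseline")
  point <- matrix(110, 2, 3)
  anom <- compute_anomaly(point, baseline, latitudes = c(40, 40))
  expect_true(all(anom == -10))
  expect_true(all(compute_anomaly(point + 7, baseline, c(40, 40)) == anom + 7))
  exact <- matrix(predict_baseline(baseline, c(45, 40)), 2, 3)
  expect_true(all(compute_anomaly(exact, baseline, c(45, 40)) == 0))
})

test_that("range masking blanks every layer outside the species range", {
  grids <- summarize_members(lapply(c(95, 100, 105), function(v) matrix(as.integer(v), 4, 4)))
  grids$anomaly <- matrix(1, 4, 4)
  mk <- function(mask) apply_range_mask(grids, mask, "sp", "budburst", 40,
                                        lats = seq(45, 42, length.out = 4),
                                        lons = seq(-100, -97, length.out = 4),
                                        ref_year = 2019)
  full <- mk(matrix(TRUE, 4, 4))
  expect_true(all(full$prediction == 100))

  none <- mk(matrix(FALSE, 4, 4))
  expect_true(all(is.na(none$prediction)) && all(is.na(none$anomaly)))

  checker <- synth_range_mask(4, 4, "checkerboard")
  half <- mk(checker)
  expect_equal(sum(is.na(half$prediction)), 8)
  expect_equal(sum(!is.na(half$sd)), 8)

  expect_error(mk(matrix(TRUE, 3, 3)), "shape")
})

test_that("defined cells always satisfy the interval ordering", {
  withr::with_seed(66, {
    grids <- lapply(1:5, function(i) {
      matrix(as.integer(round(100 + rnorm(16, 0, 6))), 4, 4)
    })
  })
  s <- summarize_members(grids)
  ok <- !is.na(s$point_estimate)
  expect_true(all(s$sd[ok] >= 0))
  expect_true(all(s$pi_low[ok] <= s$point_estimate[ok]))
  expect_true(all(s$pi_high[ok] >= s$point_estimate[ok]))
})
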