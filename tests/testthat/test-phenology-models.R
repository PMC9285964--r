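test_that("forcing accumulates linearly for thermal time and floors at zero", {
  s <- const_series(10)
  fu <- forcing_units(s, tt_model(T_base = 0, F_star = 100))
  expect_equal(fu$forcing, 10 * seq_len(120))

  frozen <- forcing_units(const_series(5), tt_model(T_base = 5, F_star = 100))
  expect_true(all(frozen$forcing == 0))
})

test_that("uniforc daily unit is 0.5 at the sigmoid midpoint", {
  u <- phenology_model("uniforc", list(t1 = 1, b_sig = -1, c_sig = 10, F_star = 20))
  fu <- forcing_units(const_series(10), u)
  expect_equal(fu$unit, rep(0.5, 120))
})

test_that("cumulative forcing is non-decreasing for every forcing family", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      s <- temperature_series(runif(150, -15, 30), start_day = -30L)
      models <- list(
        tt_model(t1 = -10, T_base = 5, F_star = 200),
        phenology_model("alternating", list(t1 = -10, a = 100, b = 500, c = -0.05)),
        phenology_model("uniforc", list(t1 = -10, b_sig = -0.5, c_sig = 8, F_star = 30))
      )
      for (m in models) {
        expect_true(all(diff(forcing_units(s, m)$forcing) >= 0))
      }
    }
  })
})

test_that("thermal time event day matches the cumulative-sum oracle", {
  expect_equal(predict_event_day(const_series(10), tt_model(F_star = 100)), 10L)

  # step-5 ramp: cumulative 0, 5, 15, 30, 50, 75, 105 -> crosses 100 on day 7
  ramp <- temperature_series(seq(0, 60, by = 5), start_day = 1L)
  expect_equal(predict_event_day(ramp, tt_model(F_star = 100)), 7L)

  # independent oracle: first day the running sum reaches the requirement
  withr::with_seed(21, {
    temps <- runif(200, 0, 25)
    oracle <- which(cumsum(pmax(temps - 4, 0)) >= 350)[1]
    s <- temperature_series(temps, start_day = 1L)
    expect_equal(predict_event_day(s, tt_model(T_base = 4, F_star = 350)), oracle)
  })
})

test_that("no event is reported when forcing can never reach the requirement", {
  expect_true(is.na(predict_event_day(const_series(3), tt_model(T_base = 5))))
  # F* -> 0+ fires at t1; F* -> infinity never fires
  expect_equal(predict_event_day(const_series(10), tt_model(F_star = 1e-9)), 1L)
  expect_true(is.na(predict_event_day(const_series(10), tt_model(F_star = 1e6))))
})

test_that("warming never delays a thermal time event", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      temps <- runif(180, -5, 25)
      m <- tt_model(T_base = 5, F_star = runif(1, 50, 400))
      base <- predict_event_day(temperature_series(temps, 1L), m)
      warm <- predict_event_day(temperature_series(temps + 2, 1L), m)
      if (!is.na(base)) {
        expect_false(is.na(warm))
        expect_lte(warm, base)
      }
    }
  })
})

test_that("alternating model matches a direct day-by-day oracle", {
  alternating_oracle <- function(temps, t1, a, b, cc, chill) {
    ncd <- 0; forcing <- 0
    for (d in seq(t1, length(temps))) {
      if (temps[d] < chill) ncd <- ncd + 1
      forcing <- forcing + max(temps[d], 0)
      if (forcing >= a + b * exp(cc * ncd)) return(d)
    }
    NA_integer_
  }
  withr::with_seed(41, {
    for (rep in 1:5) {
      temps <- runif(200, -10, 20)
      m <- phenology_model("alternating",
                           list(t1 = 1, a = 80, b = 600, c = -0.08, chill_threshold = 5))
      expect_equal(
        predict_event_day(temperature_series(temps, 1L), m),
        alternating_oracle(temps, 1, 80, 600, -0.08, 5)
      )
    }
  })
})

test_that("linear family is a rounded regression on the window mean", {
  m <- phenology_model("linear", list(beta0 = 40, beta1 = 5,
                                      window_start = 1, window_end = 60))
  s <- const_series(10.3, n = 200)
  expect_equal(predict_event_day(s, m), round(40 + 5 * 10.3))
})

test_that("series not covering t1 raises a coverage error", {
  s <- temperature_series(rep(10, 50), start_day = 20L)
  expect_error(predict_event_day(s, tt_model(t1 = 1)), "coverage")
  expect_error(forcing_units(s, tt_model(t1 = 1)), "coverage")
})

test_that("short gaps are interpolated, long gaps make the prediction missing", {
  temps <- rep(10, 100)
  temps[40:42] <- NA  # 3-day gap: interpolated
  s <- temperature_series(temps, 1L)
  expect_equal(predict_event_day(s, tt_model(F_star = 500)), 50L)

  temps[40:44] <- NA  # 5-day gap: unresolvable
  s_long <- temperature_series(temps, 1L)
  expect_true(is.na(predict_event_day(s_long, tt_model(F_star = 500))))
})

test_that("gridded prediction equals the per-cell loop oracle", {
  cube <- synth_temperature_cube(5, nlat = 5, nlon = 5, noise_sd = 2)
  m <- tt_model(T_base = 2, F_star = 300)
  g <- predict_grid(cube, m)
  oracle <- sapply(1:5, function(j) {
    sapply(1:5, function(i) predict_event_day(cell_series(cube, i, j), m))
  })
  expect_equal(unname(g[, ]), oracle)
})

test_that("grid predictions are spatially uniform for a uniform cube and ordered by warmth", {
  v <- array(10, c(2, 2, 60))
  cube <- temperature_cube(v, c(45, 44), c(-100, -99), 1:60, 2019)
  g <- predict_grid(cube, tt_model(F_star = 100))
  expect_true(all(g == 10L))

  v[2, 2, ] <- 5  # one cooler cell
  cube2 <- temperature_cube(v, c(45, 44), c(-100, -99), 1:60, 2019)
  g2 <- predict_grid(cube2, tt_model(F_star = 100))
  expect_true(all(g2[2, 2] >= g2[-4]))
})

test_that("all-missing cells are flagged missing rather than silently predicted", {
  v <- array(10, c(2, 2, 80))
  v[1, 2, ] <- NA
  cube <- temperature_cube(v, c(45, 44), c(-100, -99), 1:80, 2019)
  g <- predict_grid(cube, tt_model(F_star = 100))
  expect_true(is.na(g[1, 2]))
  expect_true(attr(g, "missing")[1, 2])
  expect_false(attr(g, "missing")[1, 1])
})

test_that("model construction rejects invalid parameters", {
  expect_error(phenology_model("thermal_time", list(t1 = 1, T_base = 0)), "F_star")
  expect_error(phenology_model("thermal_time", list(t1 = 1, T_base = 0, F_star = -5)), "F_star")
  expect_error(phenology_model("uniforc", list(t1 = 1, b_sig = 1, c_sig = 10, F_star = 5)), "b_sig")
  expect_error(phenology_model("linear", list(beta0 = 1, beta1 = 1,
                                              window_start = 60, window_end = 10)), "window")
  expect_error(phenology_model("thermal_time", list(t1 = 1, T_base = NaN, F_star = 10)), "finite")
})
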