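make_product <- function(prediction, sd = 1, issue_day = 10,
                         species = "sp", phenophase = "budburst",
                         lats = c(45, 44), lons = c(-100, -99),
                         mask = NULL) {
  n <- length(lats) * length(lons)
  pred <- matrix(as.numeric(prediction), length(lats), length(lons))
  sdm <- matrix(as.numeric(sd), length(lats), length(lons))
  mask <- mask %||% matrix(TRUE, length(lats), length(lons))
  apply_range_mask(
    list(point_estimate = pred, sd = sdm,
         pi_low = pred - 1.96 * sdm, pi_high = pred + 1.96 * sdm,
         anomaly = pred * 0),
    mask, species, phenophase, issue_day, lats, lons, 2019
  )
}

test_that("forecast lookup returns the nearest cell with ties to the lower index", {
  pr <- make_product(matrix(c(1, 2, 3, 4), 2, 2))
  hit <- lookup_forecast(pr, 45, -100)
  expect_equal(hit$prediction, 1)
  # exact midpoint in both coordinates: lower index wins
  mid <- lookup_forecast(pr, 44.5, -99.5)
  expect_equal(mid$prediction, 1)
  # nearest-cell assignment agrees with brute-force distance enumeration
  pts <- expand.grid(lat = seq(44, 45, by = 0.26), lon = seq(-100, -99, by = 0.26))
  got <- lookup_forecast(pr, pts$lat, pts$lon)$prediction
  brute <- mapply(function(la, lo) {
    cells <- expand.grid(i = 1:2, j = 1:2)
    d <- (pr$lats[cells$i] - la)^2 + (pr$lons[cells$j] - lo)^2
    k <- which.min(d)
    pr$prediction[cells$i[k], cells$j[k]]
  }, pts$lat, pts$lon)
  expect_equal(got, unname(brute))
  expect_error(lookup_forecast(pr, 50, -100), "outside")
})

test_that("verification reproduces hand-computed scores", {
  pr <- make_product(c(10, 20, 10, 20), sd = 2, issue_day = 1)
  events <- tibble::tibble(
    latitude = c(45, 44), longitude = c(-100, -100),
    species = "sp", phenophase = "budburst",
    observed_doy = c(13, 16)
  )
  vt <- verify_forecasts(list(pr), events)
  expect_equal(vt$n_events, 2)
  expect_equal(vt$rmse, sqrt(12.5), tolerance = 1e-12)
  expect_equal(vt$mean_error, 0.5)
  expect_equal(vt$mae, 3.5)
  expect_equal(vt$mean_sd, 2)

  perfect <- make_product(100, issue_day = 1)
  ev <- tibble::tibble(latitude = 45, longitude = -100, species = "sp",
                       phenophase = "budburst", observed_doy = 100)
  vp <- verify_forecasts(list(perfect), ev)
  expect_equal(vp$rmse, 0)
  expect_equal(vp$mean_error, 0)

  single <- make_product(105, issue_day = 1)
  vs <- verify_forecasts(list(single), ev)
  expect_equal(vs$rmse, 5)
  expect_equal(vs$mean_error, 5)
})

test_that("rmse >= mae >= |mean error| on every verification row", {
  withr::with_seed(93, {
    products <- lapply(c(5, 20, 35), function(issue) {
      make_product(round(100 + rnorm(4, 0, 8)), sd = runif(1, 0.5, 3),
                   issue_day = issue)
    })
    events <- tibble::tibble(
      latitude = rep(c(45, 44), 4), longitude = rep(c(-100, -99), each = 4),
      species = "sp", phenophase = "budburst",
      observed_doy = round(100 + rnorm(8, 0, 8))
    )
  })
  vt <- verify_forecasts(products, events)
  expect_true(all(vt$rmse >= vt$mae - 1e-12))
  expect_true(all(vt$mae >= abs(vt$mean_error) - 1e-12))
})

test_that("forecastable scope drops events that already occurred at issue", {
  pr <- make_product(100, issue_day = 50)
  events <- tibble::tibble(
    latitude = c(45, 45), longitude = c(-100, -100),
    species = "sp", phenophase = "budburst",
    observed_doy = c(40, 110)  # one before issue, one after
  )
  vt <- verify_forecasts(list(pr), events, scope = "forecastable")
  expect_equal(vt$n_events, 1)
  vt_all <- verify_forecasts(list(pr), events, scope = "all")
  expect_equal(vt_all$n_events, 2)
})

test_that("events on masked cells are dropped and counted", {
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  pr <- make_product(100, issue_day = 1, mask = mask)
  events <- tibble::tibble(
    latitude = c(45, 44), longitude = c(-100, -100),
    species = "sp", phenophase = "budburst",
    observed_doy = c(98, 102)
  )
  vt <- verify_forecasts(list(pr), events)
  expect_equal(vt$n_events, 1)
  expect_equal(vt$n_dropped, 1)
})

test_that("error distributions report signed errors and the mean absolute error", {
  pr <- make_product(c(100, 100, 100, 100), issue_day = 1)
  events <- tibble::tibble(
    latitude = c(45, 44), longitude = c(-100, -100),
    species = "sp", phenophase = "budburst",
    observed_doy = c(103, 96)  # errors -3 and +4
  )
  ed <- error_distribution(list(pr), events)
  expect_setequal(ed$error, c(-3, 4))
  expect_equal(unique(ed$mae), 3.5)

  sym <- tibble::tibble(
    latitude = c(45, 44), longitude = c(-100, -100),
    species = "sp", phenophase = "budburst",
    observed_doy = c(95, 105)  # errors +5 and -5
  )
  eds <- error_distribution(list(pr), sym)
  expect_equal(mean(eds$error), 0)
  expect_equal(unique(eds$mae), 5)

  # issue-date subsetting
  pr2 <- make_product(100, issue_day = 30)
  both <- error_distribution(list(pr, pr2), events, issue_days = 30)
  expect_equal(unique(both$issue_day), 30)
})

test_that("shrinking member spread shows up as non-increasing mean uncertainty", {
  # member spread constructed to shrink as issue date approaches the event
  products <- lapply(c(1, 30, 60), function(issue) {
    spread <- (100 - issue) / 20
    make_product(100, sd = spread, issue_day = issue)
  })
  events <- tibble::tibble(latitude = 45, longitude = -100, species = "sp",
                           phenophase = "budburst", observed_doy = 100)
  vt <- verify_forecasts(products, events)
  expect_true(all(diff(vt$mean_sd) <= 0))
})
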