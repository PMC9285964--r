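test_that("a zero-error member takes essentially all the stacking weight", {
  withr::with_seed(71, {
    y <- runif(50, 90, 130)
    pred <- cbind(y, y + 10, y - 10, y + 10)
  })
  w <- stacking_weights(pred, y)
  expect_gte(w[1], 0.99)
  expect_equal(sum(w), 1, tolerance = 1e-6)
})

test_that("members with opposite constant errors cancel at equal weight", {
  withr::with_seed(72, y <- runif(60, 90, 130))
  pred <- cbind(y + 8, y - 8, y + 40, y - 40)
  w <- stacking_weights(pred, y)
  expect_equal(w[1], 0.5, tolerance = 0.02)
  expect_equal(w[2], 0.5, tolerance = 0.02)
  expect_lt(max(w[3:4]), 0.02)
  stacked <- as.vector(pred %*% w)
  expect_lt(sqrt(mean((stacked - y)^2)), 0.5)
})

test_that("exactly tied members resolve to the uniform simplex point", {
  withr::with_seed(73, y <- runif(40, 90, 130))
  pred <- cbind(y + 5, y + 5, y + 5, y + 5)
  w <- stacking_weights(pred, y)
  expect_equal(unname(w), rep(0.25, 4), tolerance = 1e-6)
})

test_that("stacking weights always lie on the simplex", {
  withr::with_seed(74, {
    for (rep in 1:20) {
      n <- sample(10:80, 1)
      y <- runif(n, 80, 140)
      pred <- sapply(1:4, function(j) y + rnorm(n, rnorm(1, 0, 6), runif(1, 0.5, 8)))
      w <- stacking_weights(pred, y)
      expect_true(all(w >= 0))
      expect_equal(sum(w), 1, tolerance = 1e-6)
      # stacking never loses to the best member on its own objective
      member_rmse <- apply(pred, 2, function(p) sqrt(mean((p - y)^2)))
      stacked_rmse <- sqrt(mean((as.vector(pred %*% w) - y)^2))
      expect_lte(stacked_rmse, min(member_rmse) + 1e-9)
    }
  })
})

test_that("ensemble prediction is the weighted member mean rounded to a day", {
  # four linear members with fixed intercepts predict 90 / 110 / 100 / 100
  mk <- function(day) phenology_model("linear", list(beta0 = day, beta1 = 0,
                                                     window_start = 1, window_end = 10))
  mems <- list(a = mk(90), b = mk(110), c = mk(100), d = mk(100))
  s <- const_series(10, n = 200)
  ens <- function(w) structure(list(members = mems, weights = w, cv = NULL),
                               class = "stacked_ensemble")
  expect_equal(predict_ensemble(s, ens(c(0.5, 0.5, 0, 0))), 100L)
  expect_equal(predict_ensemble(s, ens(rep(0.25, 4))), 100L)
  expect_equal(predict_ensemble(s, ens(c(1, 0, 0, 0))), 90L)
  # consensus under any weights
  same <- structure(list(members = list(a = mk(100), b = mk(100), c = mk(100), d = mk(100)),
                         weights = c(0.1, 0.2, 0.3, 0.4), cv = NULL),
                    class = "stacked_ensemble")
  expect_equal(predict_ensemble(s, same), 100L)
})

test_that("non-responding members renormalize or veto the forecast by weight", {
  mk <- function(day) phenology_model("linear", list(beta0 = day, beta1 = 0,
                                                     window_start = 1, window_end = 10))
  never <- tt_model(F_star = 1e6)  # predicts no event on any bounded series
  s <- const_series(10, n = 200)
  # responders hold 0.6 of the weight: renormalized mean of 90 and 110
  ens1 <- structure(list(members = list(a = mk(90), b = mk(110), c = never),
                         weights = c(0.3, 0.3, 0.4), cv = NULL),
                    class = "stacked_ensemble")
  expect_equal(predict_ensemble(s, ens1), 100L)
  # responders hold under half the weight: no forecast
  ens2 <- structure(list(members = list(a = mk(90), b = never),
                         weights = c(0.4, 0.6), cv = NULL),
                    class = "stacked_ensemble")
  expect_true(is.na(predict_ensemble(s, ens2)))
  # all members silent: no forecast
  ens3 <- structure(list(members = list(a = never, b = never),
                         weights = c(0.5, 0.5), cv = NULL),
                    class = "stacked_ensemble")
  expect_true(is.na(predict_ensemble(s, ens3)))
})

test_that("cross-validated stacking concentrates weight on the true member", {
  prob <- make_recovery_problem(105, n = 30, noise_sd = 1)
  # truth is thermal_time; the fixed alternatives are deliberately misspecified
  wrong1 <- phenology_model("linear", list(beta0 = 60, beta1 = 0,
                                           window_start = 1, window_end = 60))
  wrong2 <- tt_model(t1 = 1, T_base = 0, F_star = 900)
  ens <- quiet(fit_stacked_ensemble(
    prob$observations, prob$temps,
    members = list("thermal_time", wrong1, wrong2),
    k = 10, fixed = list(thermal_time = list(t1 = 1)), seed = 5
  ))
  expect_gte(ens$weights[["thermal_time"]], 0.8)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-6)
  expect_lte(ens$cv$stacked_rmse, min(ens$cv$member_rmse) + 1e-9)
  # fold bookkeeping: one out-of-fold prediction per observation per member
  expect_false(anyNA(ens$cv$oof[, "thermal_time"]))
  expect_equal(dim(ens$cv$oof), c(30, 3))
})

test_that("fold count degrades to leave-one-out with a warning when k exceeds n", {
  prob <- make_recovery_problem(106, n = 8, noise_sd = 0, nlat = 4, nlon = 4)
  expect_warning(
    ens <- suppressMessages(fit_stacked_ensemble(
      prob$observations, prob$temps, members = list("linear"),
      k = 100, seed = 2
    )),
    "leave-one-out"
  )
  expect_equal(ens$cv$k, nrow(prob$observations))
})

test_that("held-out accuracy of the stacked ensemble tracks the observation noise", {
  prob <- make_recovery_problem(107, n = 40, noise_sd = 2)
  train <- prob$observations[1:30, ]
  test <- prob$observations[31:40, ]
  ens <- quiet(fit_stacked_ensemble(train, prob$temps,
                                    members = c("thermal_time", "linear"),
                                    k = 10, fixed = list(thermal_time = list(t1 = 1)),
                                    seed = 8))
  preds <- vapply(test$site_id, function(sid) {
    as.numeric(predict_ensemble(prob$temps[[sid]], ens))
  }, double(1))
  held_out_rmse <- sqrt(mean((preds - test$onset_doy)^2))
  expect_lte(held_out_rmse, 2 * 1.5)
})
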