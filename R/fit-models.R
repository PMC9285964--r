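#' Default parameter bounds for model fitting
#'
#' Box constraints for the bounded global search in [fit_single_model()].
#' Days are extended day indices; temperatures degrees C. The bounds are
#' deliberately wide for temperate spring phenophases: start days from early
#' November of the prior year to mid spring, base temperatures spanning the
#' usual 0-10 C literature values, and forcing requirements covering both
#' early understory species and late-leafing trees.
#'
#' @param family Model family name.
#' @return A named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function(family) {
  switch(match.arg(family, pheno_families()),
    thermal_time = list(t1 = c(-60, 100), T_base = c(-5, 15), F_star = c(10, 2000)),
    alternating  = list(t1 = c(-60, 60), a = c(0, 1000), b = c(0, 2500), c = c(-2, -0.001)),
    uniforc      = list(t1 = c(-60, 100), b_sig = c(-5, -0.05), c_sig = c(0, 25), F_star = c(5, 300)),
    linear       = list(beta0 = c(-Inf, Inf), beta1 = c(-Inf, Inf))
  )
}

#' Control settings for the global optimizer
#'
#' @param np Population size of the differential-evolution search.
#' @param itermax Maximum generations.
#' @param reltol Relative convergence tolerance on the objective.
#' @param steptol Generations without improvement before stopping.
#' @return A list of settings passed to the optimizer.
#' @export
fit_control <- function(np = 40, itermax = 120, reltol = 1e-4, steptol = 25) {
  list(np = np, itermax = itermax, reltol = reltol, steptol = steptol)
}

# Cost, in days of error, charged when a candidate parameter set predicts no
# event for an observation. Large but finite so the search can move off
# degenerate regions.
NO_EVENT_PENALTY <- 365

# Build the n_obs x n_day temperature matrix shared by all fitting
# routines. `temps` is a named list of temp_series keyed by site_id; all
# series must share a common day axis covering [day_min, day_max].
obs_temperature_matrix <- function(obs, temps) {
  ids <- as.character(obs$site_id)
  missing_ids <- setdiff(unique(ids), names(temps))
  if (length(missing_ids)) {
    abort(paste0("no temperature series for site(s): ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  day0 <- max(vapply(temps[unique(ids)], function(s) s$start_day, integer(1)))
  day1 <- min(vapply(temps[unique(ids)], function(s) s$start_day + length(s$values) - 1L, integer(1)))
  if (day1 <= day0) abort("temperature series do not share a common day window.")
  days <- day0:day1
  tm <- vapply(ids, function(id) {
    s <- temps[[id]]
    s$values[match(days, series_days(s))]
  }, double(length(days)))
  list(tm = t(tm), day0 = day0)
}

rmse <- function(x) sqrt(mean(x^2))

# Objective: RMSE of predicted vs observed onset days with NO_EVENT charged
# a large finite penalty. `par` is the vector of free parameters in bounds
# order; fixed parameters are spliced back in. Constructs the model list
# directly (parameters are already inside validated bounds) to keep the
# inner loop lean.
fit_objective <- function(par, free_names, fixed, family, tm, day0, observed) {
  params <- c(as.list(par), fixed)
  names(params)[seq_along(par)] <- free_names
  if (!is.null(params$t1)) params$t1 <- as.integer(round(params$t1))
  model <- structure(list(family = family, params = params), class = "pheno_model")
  pred <- try(predict_days_matrix(tm, day0, model), silent = TRUE)
  if (inherits(pred, "try-error")) return(1e6)
  err <- as.numeric(pred) - observed
  err[is.na(err)] <- NO_EVENT_PENALTY
  rmse(err)
}

#' Fit one phenology model to a group of onset observations
#'
#' Estimates the parameters of a single model family by minimizing the RMSE
#' between predicted and observed onset days over a species-phenophase
#' group, using a seeded, bounded differential-evolution search. The
#' forcing-model objective is a step function of its parameters (the
#' predicted day moves in whole-day jumps), so a stochastic global search is
#' used rather than a derivative-based optimizer. The `linear` family has a
#' smooth quadratic objective and is fit directly by ordinary least squares.
#'
#' Candidate parameter sets that predict no event for an observation are
#' charged a large finite penalty (365 days of error) so the search is
#' repelled from, but not trapped by, degenerate regions.
#'
#' @param obs Onset-event tibble (one species-phenophase group) with
#'   columns `site_id` and `onset_doy`.
#' @param temps Named list of [temperature_series()] keyed by `site_id`,
#'   each covering the search window.
#' @param family Model family to fit.
#' @param bounds Named list of `c(lower, upper)` pairs; defaults to
#'   [default_bounds()]. Parameters listed in `fixed` need no bounds.
#' @param fixed Named list of parameters to hold fixed (e.g.
#'   `list(t1 = 1)`).
#' @param control Optimizer settings from [fit_control()].
#' @param seed Integer seed making the stochastic search reproducible.
#'
#' @return A [phenology_model()] with a `fit` attribute carrying `n_obs`,
#'   `rmse` (training RMSE, days), `seed` and `family`.
#' @export
fit_single_model <- function(obs, temps, family, bounds = NULL,
                             fixed = list(), control = fit_control(),
                             seed = 1L) {
  family <- match.arg(family, pheno_families())
  if (nrow(obs) < 2) abort("need at least 2 observations to fit a model.")
  mt <- obs_temperature_matrix(obs, temps)
  observed <- as.numeric(obs$onset_doy)

  if (family == "linear") {
    fixed <- modifyList(list(window_start = 1L, window_end = 60L), fixed)
    model <- fit_linear_family(mt, observed, fixed)
  } else {
    bounds <- bounds %||% default_bounds(family)
    if (family == "alternating" && is.null(fixed$chill_threshold)) {
      fixed$chill_threshold <- 5
    }
    free_names <- setdiff(pheno_param_names(family), names(fixed))
    bounds <- bounds[free_names]
    if (any(vapply(bounds, is.null, logical(1)))) {
      abort("missing bounds for one or more free parameters.")
    }
    lower <- vapply(bounds, `[`, double(1), 1)
    upper <- vapply(bounds, `[`, double(1), 2)
    if (any(!is.finite(c(lower, upper)))) abort("search space must be bounded.")
    withr::with_seed(seed, {
      # DEoptim advises NP >= 10 * dim on every call; the lighter
      # cross-validation settings are intentional, so keep it quiet
      de <- suppressWarnings(DEoptim::DEoptim(
        fn = fit_objective,
        lower = lower, upper = upper,
        control = DEoptim::DEoptim.control(
          NP = control$np, itermax = control$itermax,
          reltol = control$reltol, steptol = control$steptol,
          trace = FALSE
        ),
        free_names = free_names, fixed = fixed, family = family,
        tm = mt$tm, day0 = mt$day0, observed = observed
      ))
    })
    params <- c(as.list(de$optim$bestmem), fixed)
    names(params)[seq_along(free_names)] <- free_names
    model <- phenology_model(family, params)
  }

  pred <- predict_days_matrix(mt$tm, mt$day0, model)
  err <- as.numeric(pred) - observed
  err[is.na(err)] <- NO_EVENT_PENALTY
  attr(model, "fit") <- list(family = family, n_obs = nrow(obs),
                             rmse = rmse(err), seed = seed)
  model
}

# Exact least-squares fit of the linear family (objective is quadratic in
# beta0, beta1 up to the final rounding).
fit_linear_family <- function(mt, observed, fixed) {
  days <- mt$day0 + seq_len(ncol(mt$tm)) - 1L
  keep <- days >= fixed$window_start & days <= fixed$window_end
  if (!any(keep)) abort("temperature series do not cover the linear-model window.")
  mean_t <- rowMeans(mt$tm[, keep, drop = FALSE])
  if (stats::var(mean_t) < 1e-12) {
    co <- c(mean(observed), 0)
  } else {
    co <- coef(lm(observed ~ mean_t))
  }
  phenology_model("linear", list(
    beta0 = unname(co[1]), beta1 = unname(co[2]),
    window_start = fixed$window_start, window_end = fixed$window_end
  ))
}

#' Fit the latitude-only baseline model
#'
#' Ordinary least squares of onset day on site latitude. The baseline
#' provides the long-term, spatially corrected average event date against
#' which forecast anomalies are computed.
#'
#' @param obs Onset-event tibble with columns `latitude` and `onset_doy`.
#' @return An object of class `latitude_baseline` with coefficients
#'   `beta0` (day) and `beta1` (day per degree latitude).
#' @export
fit_latitude_baseline <- function(obs) {
  if (length(unique(obs$latitude)) < 2) {
    abort("latitude baseline needs at least 2 distinct latitudes.")
  }
  fit <- lm(onset_doy ~ latitude, data = obs)
  co <- coef(fit)
  structure(
    list(beta0 = unname(co[1]), beta1 = unname(co[2]),
         n_obs = nrow(obs), sigma = summary(fit)$sigma,
         se = summary(fit)$coefficients[, "Std. Error"]),
    class = "latitude_baseline"
  )
}

#' @export
print.latitude_baseline <- function(x, ...) {
  cat(sprintf("<latitude_baseline> day = %.2f %+.3f * latitude (n = %d)\n",
              x$beta0, x$beta1, x$n_obs))
  invisible(x)
}

#' @rdname fit_latitude_baseline
#' @param baseline A `latitude_baseline`.
#' @param latitude Numeric vector or matrix of latitudes.
#' @return `predict_baseline()` returns expected event days (not rounded).
#' @export
predict_baseline <- function(baseline, latitude) {
  stopifnot(inherits(baseline, "latitude_baseline"))
  baseline$beta0 + baseline$beta1 * latitude
}
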