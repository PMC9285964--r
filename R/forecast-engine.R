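#' Splice observed and forecast temperatures into one climate member
#'
#' A forecast of a spring event needs temperatures for the whole
#' accumulation season: observed values from the prior autumn up to the
#' issue date, and downscaled forecast values from the issue date onward.
#' This concatenates the two cubes into one continuous daily member,
#' recording the provenance of every day. Where the cubes overlap the
#' forecast values win (the observed archive may lag by a day or two).
#'
#' @param observed Fine-grid daily [temperature_cube()] covering the
#'   season start through at least `issue_day - 1`.
#' @param downscaled Fine-grid daily [temperature_cube()] covering
#'   `issue_day` onward.
#' @param issue_day Extended day index the forecast was issued.
#' @param member_id Optional member identifier.
#' @return An object of class `climate_member`: `cube` (the spliced
#'   [temperature_cube()]), `provenance` (`"observed"`/`"forecast"` per
#'   day), `issue_day`, `member_id`.
#' @export
assemble_member <- function(observed, downscaled, issue_day, member_id = NA_integer_) {
  stopifnot(inherits(observed, "temp_cube"), inherits(downscaled, "temp_cube"))
  if (!isTRUE(all.equal(observed$lats, downscaled$lats)) ||
      !isTRUE(all.equal(observed$lons, downscaled$lons))) {
    abort("observed and downscaled cubes are on different grids.")
  }
  issue_day <- as.integer(issue_day)
  obs_days <- observed$days[observed$days < issue_day]
  fc_days <- downscaled$days[downscaled$days >= issue_day]
  days <- c(obs_days, fc_days)
  if (length(days) == 0L) abort("no days available around the issue date.")
  gaps <- setdiff(seq(min(days), max(days)), days)
  if (length(gaps)) {
    abort(sprintf("coverage gap at the observed/forecast splice: missing day(s) %s.",
                  paste(head(gaps, 10), collapse = ", ")))
  }
  vals <- array(NA_real_, c(length(observed$lats), length(observed$lons), length(days)))
  vals[, , seq_along(obs_days)] <- observed$values[, , match(obs_days, observed$days)]
  vals[, , length(obs_days) + seq_along(fc_days)] <-
    downscaled$values[, , match(fc_days, downscaled$days)]
  structure(
    list(cube = temperature_cube(vals, observed$lats, observed$lons, days, observed$ref_year),
         provenance = rep(c("observed", "forecast"), c(length(obs_days), length(fc_days))),
         issue_day = issue_day, member_id = member_id),
    class = "climate_member"
  )
}

#' @export
print.climate_member <- function(x, ...) {
  cat(sprintf("<climate_member> member %s, issued day %d, days %d..%d (%d observed, %d forecast)\n",
              as.character(x$member_id), x$issue_day, x$cube$days[1],
              x$cube$days[length(x$cube$days)],
              sum(x$provenance == "observed"), sum(x$provenance == "forecast")))
  invisible(x)
}

#' Run the phenology ensemble over each climate member
#'
#' @param members List of `climate_member` objects (nominally 5).
#' @param ensemble A `stacked_ensemble`.
#' @return List of predicted-day grids (one per member), as returned by
#'   [predict_ensemble()].
#' @export
run_member_forecasts <- function(members, ensemble) {
  if (length(members) < 1L) abort("at least one climate member is required.")
  lapply(members, function(m) {
    cube <- if (inherits(m, "climate_member")) m$cube else m
    predict_ensemble(cube, ensemble)
  })
}

#' Summarize member predictions into a forecast with uncertainty
#'
#' The point estimate at each cell is the mean predicted day across the
#' climate members (rounded to a whole day); the uncertainty is their
#' sample standard deviation (n - 1 denominator), which captures the
#' spread induced by the climate forecast members; the 95% prediction
#' interval is the normal approximation `point +/- 1.96 * sd`, optionally
#' clipped to the forecast day span. Cells where fewer than
#' `ceiling(0.6 * n)` members (3 of 5) respond are missing; cells with a
#' minority of non-responding members are summarized over the responders
#' and flagged `partial`.
#'
#' @param member_grids List of >= 2 predicted-day grids from
#'   [run_member_forecasts()].
#' @param span Optional `c(first, last)` extended day indices to clip the
#'   prediction interval to (the span of the climate members).
#' @return A list of matrices: `point_estimate`, `sd`, `pi_low`,
#'   `pi_high`, `partial` (logical), `n_members`.
#' @export
summarize_members <- function(member_grids, span = NULL) {
  n <- length(member_grids)
  if (n < 2L) abort("need at least 2 members to estimate forecast spread.")
  arr <- simplify2array(lapply(member_grids, function(g) {
    g2 <- g; attributes(g2) <- attributes(g)["dim"]; g2
  }))
  n_resp <- apply(!is.na(arr), c(1, 2), sum)
  min_resp <- max(2L, ceiling(0.6 * n))
  point <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  sdev <- apply(arr, c(1, 2), sd, na.rm = TRUE)
  ok <- n_resp >= min_resp
  point[!ok] <- NA_real_
  sdev[!ok] <- NA_real_
  point <- round(point)
  lo <- point - 1.96 * sdev
  hi <- point + 1.96 * sdev
  if (!is.null(span)) {
    lo <- pmax(lo, span[1])
    hi <- pmin(hi, span[2])
  }
  list(point_estimate = point, sd = sdev, pi_low = lo, pi_high = hi,
       partial = ok & n_resp < n, n_members = n)
}

#' Forecast anomaly relative to the latitude baseline
#'
#' The anomaly is the predicted date minus the long-term, spatially
#' corrected average date from the latitude-only baseline model; negative
#' values mean earlier than average.
#'
#' @param point_estimate Predicted-day grid.
#' @param baseline A `latitude_baseline` from [fit_latitude_baseline()].
#' @param latitudes Latitude of each grid row (vector) or a full latitude
#'   grid (matrix).
#' @return Anomaly grid, days.
#' @export
compute_anomaly <- function(point_estimate, baseline, latitudes) {
  expected <- predict_baseline(baseline, latitudes)
  if (is.matrix(expected)) point_estimate - expected
  else point_estimate - matrix(expected, nrow(point_estimate), ncol(point_estimate))
}

#' Assemble and crop a forecast product to a species range
#'
#' Bundles the summarized grids and anomaly into a forecast product and
#' masks every grid to the species range: cells outside the range mask are
#' missing in every layer.
#'
#' @param grids List from [summarize_members()] plus an `anomaly` element.
#' @param mask Logical matrix, `TRUE` inside the species range.
#' @param species,phenophase,issue_day,ref_year Product metadata.
#' @param lats,lons Grid coordinates.
#' @param model_version Optional version string stored with the product.
#' @return An object of class `forecast_product` with matrices
#'   `prediction`, `sd`, `pi_low`, `pi_high`, `anomaly`, logical `mask`.
#' @export
apply_range_mask <- function(grids, mask, species, phenophase, issue_day,
                             lats, lons, ref_year, model_version = "0.1.0") {
  layers <- list(prediction = grids$point_estimate, sd = grids$sd,
                 pi_low = grids$pi_low, pi_high = grids$pi_high,
                 anomaly = grids$anomaly)
  dims <- dim(layers$prediction)
  if (!all(dim(mask) == dims)) abort("range mask shape does not match forecast grids.")
  layers <- lapply(layers, function(g) { g[!mask] <- NA_real_; g })
  structure(
    c(layers,
      list(mask = mask, species = species, phenophase = phenophase,
           issue_day = as.integer(issue_day), ref_year = as.integer(ref_year),
           lats = lats, lons = lons, model_version = model_version)),
    class = "forecast_product"
  )
}

#' @export
print.forecast_product <- function(x, ...) {
  cat(sprintf("<forecast_product> %s / %s, issued day %d (%d): %d x %d cells, %d in range\n",
              x$species, x$phenophase, x$issue_day, x$ref_year,
              length(x$lats), length(x$lons), sum(x$mask)))
  invisible(x)
}

#' @export
as_tibble.forecast_product <- function(x, ...) {
  nlat <- length(x$lats); nlon <- length(x$lons)
  tibble(
    species = x$species, phenophase = x$phenophase, issue_day = x$issue_day,
    lat = rep(x$lats, times = nlon),
    lon = rep(x$lons, each = nlat),
    prediction = as.vector(x$prediction),
    sd = as.vector(x$sd),
    pi_low = as.vector(x$pi_low),
    pi_high = as.vector(x$pi_high),
    anomaly = as.vector(x$anomaly),
    in_range = as.vector(x$mask)
  )
}
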