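#' Look up a forecast at a point location
#'
#' Returns the forecast values at the grid cell nearest to the given
#' coordinates (ties broken toward the lower index). Vectorised over
#' locations.
#'
#' @param product A `forecast_product`.
#' @param latitude,longitude Coordinates of the event site(s), decimal
#'   degrees, inside the grid bounds (within half a cell of the edge
#'   centers).
#' @return A tibble with columns `latitude`, `longitude`, `prediction`,
#'   `sd`, `in_range`. Masked or missing cells have `NA` prediction.
#' @export
lookup_forecast <- function(product, latitude, longitude) {
  stopifnot(inherits(product, "forecast_product"))
  lat_step <- if (length(product$lats) > 1) abs(diff(product$lats[1:2])) else 1
  lon_step <- if (length(product$lons) > 1) abs(diff(product$lons[1:2])) else 1
  out_of_bounds <- latitude > max(product$lats) + lat_step / 2 |
    latitude < min(product$lats) - lat_step / 2 |
    longitude > max(product$lons) + lon_step / 2 |
    longitude < min(product$lons) - lon_step / 2
  if (any(out_of_bounds)) {
    abort(sprintf("%d location(s) outside the forecast grid bounds.", sum(out_of_bounds)))
  }
  i <- vapply(latitude, function(x) which.min(abs(product$lats - x)), integer(1))
  j <- vapply(longitude, function(x) which.min(abs(product$lons - x)), integer(1))
  cells <- cbind(i, j)
  tibble(
    latitude = latitude, longitude = longitude,
    prediction = product$prediction[cells],
    sd = product$sd[cells],
    in_range = product$mask[cells]
  )
}

#' Verify forecasts against observed events
#'
#' Scores each issue date's forecast products against events that were
#' subsequently observed: root mean square error, mean forecast
#' uncertainty (the member-spread standard deviation), and mean signed
#' error (positive = predicted later than observed). Events are matched to
#' forecasts by species, phenophase and nearest grid cell; events falling
#' on masked-out or missing cells are dropped (their count is reported in
#' the `n_dropped` column).
#'
#' With `scope = "forecastable"` (default) each issue date is scored
#' against the events that had not yet occurred at issue — the events the
#' forecast could still inform; `scope = "all"` scores every matched event
#' regardless of timing.
#'
#' @param products List of `forecast_product` objects (any mix of species,
#'   phenophases and issue days).
#' @param events Tibble of observed events with columns `latitude`,
#'   `longitude`, `species`, `phenophase`, `observed_doy`.
#' @param scope `"forecastable"` or `"all"` (see Details).
#' @return A tibble with one row per issue day: `issue_day`, `n_events`,
#'   `n_dropped`, `rmse`, `mean_sd`, `mean_error`, `mae`.
#' @export
verify_forecasts <- function(products, events, scope = c("forecastable", "all")) {
  scope <- match.arg(scope)
  matched <- match_events(products, events, scope)
  matched |>
    dplyr::group_by(.data$issue_day) |>
    dplyr::summarise(
      n_events = sum(!is.na(.data$error)),
      n_dropped = sum(is.na(.data$error)),
      rmse = if (any(!is.na(.data$error))) rmse(.data$error[!is.na(.data$error)]) else NA_real_,
      mean_sd = mean(.data$sd[!is.na(.data$error)]),
      mean_error = mean(.data$error, na.rm = TRUE),
      mae = mean(abs(.data$error), na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_error = ifelse(.data$n_events == 0, NA_real_, .data$mean_error),
      mae = ifelse(.data$n_events == 0, NA_real_, .data$mae),
      mean_sd = ifelse(.data$n_events == 0, NA_real_, .data$mean_sd)
    )
}

# One row per (issue day, event) with signed error; NA error = event
# matched a masked/missing cell or an ensemble non-forecast.
match_events <- function(products, events, scope) {
  rows <- lapply(products, function(pr) {
    ev <- events |>
      dplyr::filter(.data$species == pr$species, .data$phenophase == pr$phenophase)
    if (scope == "forecastable") ev <- dplyr::filter(ev, .data$observed_doy >= pr$issue_day)
    if (nrow(ev) == 0) {
      return(tibble(issue_day = pr$issue_day, error = double(), sd = double()))
    }
    hit <- lookup_forecast(pr, ev$latitude, ev$longitude)
    tibble(
      issue_day = pr$issue_day,
      error = as.numeric(hit$prediction) - as.numeric(ev$observed_doy),
      sd = hit$sd
    )
  })
  dplyr::bind_rows(rows)
}

#' Distribution of forecast errors for selected issue dates
#'
#' Collects the signed errors (predicted minus observed) for each selected
#' issue date, with the mean absolute error per date, for inspecting the
#' error distribution as the season progresses.
#'
#' @inheritParams verify_forecasts
#' @param issue_days Subset of issue days to include; `NULL` for all.
#' @return A tibble with columns `issue_day`, `error`, and a per-date
#'   `mae` column (repeated within date).
#' @export
error_distribution <- function(products, events, issue_days = NULL,
                               scope = c("forecastable", "all")) {
  scope <- match.arg(scope)
  if (!is.null(issue_days)) {
    products <- Filter(function(p) p$issue_day %in% issue_days, products)
  }
  match_events(products, events, scope) |>
    dplyr::filter(!is.na(.data$error)) |>
    dplyr::group_by(.data$issue_day) |>
    dplyr::mutate(mae = mean(abs(.data$error))) |>
    dplyr::ungroup() |>
    dplyr::select("issue_day", "error", "mae")
}
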