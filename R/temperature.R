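#' Daily temperature series
#'
#' A contiguous series of daily mean 2-m temperatures (degrees C) on the
#' extended day axis (see [day_to_date()]). Missing days are `NA`; values
#' must be finite and within \[-60, 60\] degrees C. This is the sole climate
#' driver consumed by the phenology model family.
#'
#' @param values Numeric vector of daily mean temperatures, degrees C.
#'   `NA` marks missing days.
#' @param start_day Integer extended day index of `values[1]`.
#'
#' @return An object of class `temp_series`.
#' @examples
#' s <- temperature_series(rep(10, 120), start_day = -60)
#' series_days(s)[1:3]
#' @export
temperature_series <- function(values, start_day = 1L) {
  if (!is.numeric(values) || length(values) < 1L) {
    abort("`values` must be a non-empty numeric vector.")
  }
  values <- as.double(values)
  bad <- !is.na(values) & (!is.finite(values) | values < -60 | values > 60)
  if (any(bad)) {
    abort(sprintf(
      "Temperatures must be finite and within [-60, 60] degrees C; %d value(s) violate this (first at position %d).",
      sum(bad), which(bad)[1]
    ))
  }
  structure(
    list(values = values, start_day = as.integer(start_day)),
    class = "temp_series"
  )
}

#' @rdname temperature_series
#' @param x A `temp_series`.
#' @export
series_days <- function(x) {
  stopifnot(inherits(x, "temp_series"))
  x$start_day + seq_along(x$values) - 1L
}

#' @export
print.temp_series <- function(x, ...) {
  cat(sprintf(
    "<temp_series> %d days (%d..%d), mean %.1f C, %d missing\n",
    length(x$values), x$start_day, x$start_day + length(x$values) - 1L,
    mean(x$values, na.rm = TRUE), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
as_tibble.temp_series <- function(x, ...) {
  tibble(day = series_days(x), tmean = x$values)
}

# Linear interpolation of interior NA runs of length <= max_run; longer runs
# (and leading/trailing NAs) are left missing. Gridded temperature products
# have occasional gaps; silently zero-filling them would bias forcing sums.
interpolate_gaps <- function(v, max_run = 3L) {
  if (!anyNA(v)) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    if (r$lengths[k] > max_run) next
    i0 <- starts[k] - 1L
    i1 <- ends[k] + 1L
    if (i0 < 1L || i1 > length(v)) next   # edge gap: cannot interpolate
    idx <- starts[k]:ends[k]
    v[idx] <- v[i0] + (v[i1] - v[i0]) * (idx - i0) / (i1 - i0)
  }
  v
}

#' Gridded daily temperature cube
#'
#' A latitude x longitude x time array of daily mean temperatures on the
#' extended day axis. Latitudes run north to south along the first array
#' dimension, longitudes west to east along the second; the time axis is
#' strictly consecutive daily steps.
#'
#' @param values Numeric array `[n_lat, n_lon, n_day]`, degrees C.
#' @param lats,lons Cell-center coordinates in decimal degrees; `lats`
#'   strictly decreasing, `lons` strictly increasing.
#' @param days Integer extended day indices, strictly consecutive.
#' @param ref_year Reference year anchoring day 1 of the extended axis.
#'
#' @return An object of class `temp_cube`.
#' @examples
#' cube <- temperature_cube(array(10, c(2, 2, 5)), c(45, 44), c(-100, -99),
#'                          days = 1:5, ref_year = 2019)
#' cell_series(cube, 1, 1)
#' @export
temperature_cube <- function(values, lats, lons, days, ref_year) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) abort("`values` must be a 3-d array [lat, lon, day].")
  days <- as.integer(days)
  if (length(days) != dim(values)[3]) abort("time axis length does not match `values`.")
  if (length(days) > 1L && any(diff(days) != 1L)) {
    abort("`days` must be strictly consecutive daily steps.")
  }
  if (length(lats) != dim(values)[1] || length(lons) != dim(values)[2]) {
    abort("coordinate lengths do not match `values` dimensions.")
  }
  if (length(lats) > 1L && any(diff(lats) >= 0)) abort("`lats` must be strictly decreasing (north to south).")
  if (length(lons) > 1L && any(diff(lons) <= 0)) abort("`lons` must be strictly increasing (west to east).")
  ok <- is.na(values) | (is.finite(values) & values >= -60 & values <= 60)
  if (!all(ok)) abort("cube temperatures must be finite and within [-60, 60] degrees C (or NA).")
  structure(
    list(values = values, lats = as.double(lats), lons = as.double(lons),
         days = days, ref_year = as.integer(ref_year)),
    class = "temp_cube"
  )
}

#' @export
print.temp_cube <- function(x, ...) {
  cat(sprintf(
    "<temp_cube> %d x %d cells, days %d..%d (ref year %d)\n",
    length(x$lats), length(x$lons), x$days[1], x$days[length(x$days)], x$ref_year
  ))
  invisible(x)
}

#' @rdname temperature_cube
#' @param cube A `temp_cube`.
#' @param i,j Row (latitude) and column (longitude) cell indices.
#' @export
cell_series <- function(cube, i, j) {
  stopifnot(inherits(cube, "temp_cube"))
  temperature_series(cube$values[i, j, ], start_day = cube$days[1])
}

#' @export
as_tibble.temp_cube <- function(x, ...) {
  nlat <- length(x$lats); nlon <- length(x$lons); nday <- length(x$days)
  tibble(
    lat = rep(x$lats, times = nlon * nday),
    lon = rep(rep(x$lons, each = nlat), times = nday),
    day = rep(x$days, each = nlat * nlon),
    tmean = as.vector(x$values)
  )
}

# Flatten to a cells x days matrix, cell index = i + (j - 1) * n_lat
# (column-major over the first two array dimensions).
cube_matrix <- function(cube) {
  d <- dim(cube$values)
  matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
}

matrix_to_grid <- function(v, cube) {
  matrix(v, nrow = length(cube$lats), ncol = length(cube$lons))
}

#' Sub-daily coarse forecast cube
#'
#' A coarse-resolution (e.g. 0.25 degree) temperature forecast cube on a
#' uniform 6-hour time step, as issued by a global seasonal forecast
#' system. Times are fractional extended days: hour h of extended day d is
#' `d + h/24`.
#'
#' @param values Numeric array `[n_lat, n_lon, n_time]`, degrees C.
#' @param lats,lons Coarse cell-center coordinates (degrees), `lats`
#'   decreasing, `lons` increasing.
#' @param times Fractional extended day indices at uniform 6-h (0.25 day)
#'   spacing.
#' @param ref_year Reference year anchoring day 1.
#' @param member_id Optional ensemble member identifier.
#' @param issue_day Optional extended day index the forecast was issued.
#'
#' @return An object of class `coarse_cube`.
#' @export
coarse_cube <- function(values, lats, lons, times, ref_year,
                        member_id = NA_integer_, issue_day = NA_integer_) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) abort("`values` must be a 3-d array [lat, lon, time].")
  times <- as.double(times)
  if (length(times) != dim(values)[3]) abort("time axis length does not match `values`.")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(abs(dt - 0.25) > 1e-9)) abort("`times` must be at a uniform 6-hour (0.25 day) step.")
  }
  if (length(lats) > 1L && any(diff(lats) >= 0)) abort("`lats` must be strictly decreasing.")
  if (length(lons) > 1L && any(diff(lons) <= 0)) abort("`lons` must be strictly increasing.")
  structure(
    list(values = values, lats = as.double(lats), lons = as.double(lons),
         times = times, ref_year = as.integer(ref_year),
         member_id = member_id, issue_day = issue_day),
    class = "coarse_cube"
  )
}

#' @export
print.coarse_cube <- function(x, ...) {
  cat(sprintf(
    "<coarse_cube> %d x %d cells, %d six-hour steps (days %.2f..%.2f), member %s\n",
    length(x$lats), length(x$lons), length(x$times),
    x$times[1], x$times[length(x$times)], as.character(x$member_id)
  ))
  invisible(x)
}
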