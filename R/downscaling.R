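#' Aggregate a sub-daily coarse cube to daily means
#'
#' Each day's value is the mean of its four 6-hour values; a trailing
#' partial day is dropped. Phenology models consume 24-h daily mean
#' temperature, so this is the first step in using a sub-daily forecast.
#'
#' @param cube A [coarse_cube()] on a uniform 6-h step aligned to days.
#' @return A [temperature_cube()] on the coarse grid at daily steps.
#' @export
aggregate_to_daily <- function(cube) {
  stopifnot(inherits(cube, "coarse_cube"))
  day_of <- floor(cube$times + 1e-9)
  counts <- table(day_of)
  full_days <- as.integer(names(counts)[counts == 4L])
  # partial days are only tolerated at the trailing edge
  partial <- as.integer(names(counts)[counts != 4L])
  if (length(partial) && any(partial < max(full_days))) {
    abort("interior day(s) with fewer than four 6-h steps; non-uniform time axis.")
  }
  keep <- day_of %in% full_days
  d <- dim(cube$values)
  m <- matrix(cube$values, d[1] * d[2], d[3])[, keep, drop = FALSE]
  grp <- match(day_of[keep], full_days)
  daily <- vapply(seq_along(full_days), function(g) {
    rowMeans(m[, grp == g, drop = FALSE])
  }, double(d[1] * d[2]))
  temperature_cube(array(daily, c(d[1], d[2], length(full_days))),
                   cube$lats, cube$lons, full_days, cube$ref_year)
}

# Inverse-distance-weighting design: for each fine point, the k nearest
# coarse centers and their normalized d^-p weights. Distances are Euclidean
# in degrees (the grids here span modest extents; great-circle corrections
# change the weights negligibly). Fine points outside the coarse bounding
# box fall back to the single nearest center.
idw_weights <- function(coarse_lat, coarse_lon, fine_lat, fine_lon, k = 4, p = 2) {
  if (length(coarse_lat) == 0L) abort("empty coarse field.")
  k <- min(k, length(coarse_lat))
  n_fine <- length(fine_lat)
  idx <- matrix(NA_integer_, n_fine, k)
  w <- matrix(0, n_fine, k)
  out_hull <- fine_lat > max(coarse_lat) + 1e-12 | fine_lat < min(coarse_lat) - 1e-12 |
    fine_lon > max(coarse_lon) + 1e-12 | fine_lon < min(coarse_lon) - 1e-12
  for (i in seq_len(n_fine)) {
    d2 <- (coarse_lat - fine_lat[i])^2 + (coarse_lon - fine_lon[i])^2
    if (out_hull[i]) {
      j <- which.min(d2)
      idx[i, 1] <- j; w[i, 1] <- 1
      next
    }
    nn <- order(d2)[seq_len(k)]
    idx[i, ] <- nn
    dd <- sqrt(d2[nn])
    if (dd[1] < 1e-10) {            # coincident with a coarse center
      w[i, 1] <- 1
    } else {
      wi <- dd^(-p)
      w[i, ] <- wi / sum(wi)
    }
  }
  list(idx = idx, w = w)
}

#' Inverse-distance-weighted interpolation of a coarse field
#'
#' Interpolates one coarse 2-d field to arbitrary fine points using the
#' `k` nearest coarse cell centers weighted by inverse distance to the
#' power `p`. A fine point coinciding with a coarse center returns that
#' center's value exactly; points outside the coarse bounding box use the
#' nearest center.
#'
#' @param field Numeric matrix on the coarse grid `[n_lat, n_lon]`.
#' @param coarse_lats,coarse_lons Coarse cell-center coordinates.
#' @param fine_lats,fine_lons Coordinates of the target points
#'   (equal-length vectors).
#' @param k Number of neighbors (default 4).
#' @param p Inverse-distance power (default 2).
#' @return Numeric vector of interpolated values at the fine points.
#' @export
interpolate_idw <- function(field, coarse_lats, coarse_lons,
                            fine_lats, fine_lons, k = 4, p = 2) {
  grid <- expand.grid(lat = coarse_lats, lon = coarse_lons)
  des <- idw_weights(grid$lat, grid$lon, fine_lats, fine_lons, k, p)
  v <- as.vector(field)
  out <- numeric(length(fine_lats))
  for (i in seq_along(out)) {
    j <- des$idx[i, !is.na(des$idx[i, ])]
    out[i] <- sum(v[j] * des$w[i, seq_along(j)])
  }
  out
}

#' Asynchronous regression of fine on coarse temperatures
#'
#' Regresses sorted fine-scale values on sorted coarse-scale values for one
#' calendar month: both samples are ordered ascending and paired by
#' empirical quantile (the longer sample is linearly interpolated to the
#' shorter one's length), then ordinary least squares gives a slope and
#' intercept. Pairing by rank rather than timestamp means the two archives
#' need not be synchronous — only their distributions are matched — and the
#' fit is invariant to any permutation of timestamps within the month.
#'
#' @param coarse_vals,fine_vals Daily temperature samples (degrees C) for
#'   one calendar month across the archive years; each needs >= `n_min`
#'   values.
#' @param n_min Minimum sample size (default 30).
#' @return Named numeric vector `c(slope, intercept)`.
#' @export
fit_asynchronous_regression <- function(coarse_vals, fine_vals, n_min = 30) {
  coarse_vals <- coarse_vals[!is.na(coarse_vals)]
  fine_vals <- fine_vals[!is.na(fine_vals)]
  if (length(coarse_vals) < n_min || length(fine_vals) < n_min) {
    abort(sprintf("need at least %d values in both samples.", n_min))
  }
  x <- sort(coarse_vals)
  y <- sort(fine_vals)
  n <- min(length(x), length(y))
  qs <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
  if (length(x) > n) x <- quantile_interp(x, qs)
  if (length(y) > n) y <- quantile_interp(y, qs)
  if (stats::var(x) < 1e-12) {
    abort("zero variance in sorted coarse values; asynchronous regression is degenerate.")
  }
  co <- stats::lm.fit(cbind(1, x), y)$coefficients
  c(slope = unname(co[2]), intercept = unname(co[1]))
}

# Linear interpolation of a sorted sample's empirical quantile function.
quantile_interp <- function(sorted_vals, qs) {
  n <- length(sorted_vals)
  approx(seq(0, 1, length.out = n), sorted_vals, xout = qs)$y
}

#' Build the per-cell monthly downscaling model
#'
#' For every fine-grid cell, interpolates the coarse daily archive to that
#' cell with inverse-distance weighting and fits one asynchronous
#' regression per calendar month, giving 12 slope/intercept pairs per cell.
#' Cells or months with insufficient or zero-variance data are flagged
#' missing (`NA`), never fabricated.
#'
#' @param coarse_archive Daily [temperature_cube()] on the coarse grid
#'   (use [aggregate_to_daily()] first for sub-daily archives).
#' @param fine_archive Daily [temperature_cube()] on the fine grid covering
#'   the same period.
#' @param k,p Inverse-distance weighting neighbors and power.
#' @param n_min Minimum values per cell-month regression.
#' @return An object of class `downscaling_model`: fine coordinates and
#'   `slope`/`intercept` arrays `[n_lat, n_lon, 12]`.
#' @export
build_downscaling_model <- function(coarse_archive, fine_archive, k = 4, p = 2,
                                    n_min = 30) {
  stopifnot(inherits(coarse_archive, "temp_cube"), inherits(fine_archive, "temp_cube"))
  common <- intersect(coarse_archive$days, fine_archive$days)
  if (length(common) < 365) {
    abort("coarse and fine archives must overlap by at least one full year.")
  }
  cm <- cube_matrix(coarse_archive)[, match(common, coarse_archive$days), drop = FALSE]
  fm <- cube_matrix(fine_archive)[, match(common, fine_archive$days), drop = FALSE]
  months <- day_month(common, coarse_archive$ref_year)

  grid <- expand.grid(lat = fine_archive$lats, lon = fine_archive$lons)
  cgrid <- expand.grid(lat = coarse_archive$lats, lon = coarse_archive$lons)
  des <- idw_weights(cgrid$lat, cgrid$lon, grid$lat, grid$lon, k, p)

  nlat <- length(fine_archive$lats); nlon <- length(fine_archive$lons)
  slope <- array(NA_real_, c(nlat, nlon, 12))
  intercept <- array(NA_real_, c(nlat, nlon, 12))
  for (cell in seq_len(nrow(grid))) {
    j <- des$idx[cell, !is.na(des$idx[cell, ])]
    coarse_at_cell <- as.vector(des$w[cell, seq_along(j), drop = FALSE] %*% cm[j, , drop = FALSE])
    i_lat <- ((cell - 1L) %% nlat) + 1L
    i_lon <- ((cell - 1L) %/% nlat) + 1L
    for (mo in sort(unique(months))) {
      sel <- months == mo
      fit <- try(
        fit_asynchronous_regression(coarse_at_cell[sel], fm[cell, sel], n_min = n_min),
        silent = TRUE
      )
      if (inherits(fit, "try-error")) next  # flagged missing
      slope[i_lat, i_lon, mo] <- fit["slope"]
      intercept[i_lat, i_lon, mo] <- fit["intercept"]
    }
  }
  structure(
    list(lats = fine_archive$lats, lons = fine_archive$lons,
         slope = slope, intercept = intercept, k = k, p = p),
    class = "downscaling_model"
  )
}

#' @export
print.downscaling_model <- function(x, ...) {
  n_miss <- sum(is.na(x$slope))
  cat(sprintf("<downscaling_model> %d x %d fine cells x 12 months (%d missing pairs)\n",
              length(x$lats), length(x$lons), n_miss))
  invisible(x)
}

#' Downscale a coarse forecast to the fine grid
#'
#' Aggregates the sub-daily coarse forecast to daily means, interpolates
#' each day to the fine grid with inverse-distance weighting, and applies
#' each cell's calendar-month affine correction
#' `slope * x + intercept`. Cells with missing model parameters for a
#' needed month are missing in the output.
#'
#' @param forecast A [coarse_cube()] (or an already-daily
#'   [temperature_cube()] on the coarse grid).
#' @param model A `downscaling_model` from [build_downscaling_model()].
#' @return A fine-grid daily [temperature_cube()].
#' @export
apply_downscaling <- function(forecast, model) {
  stopifnot(inherits(model, "downscaling_model"))
  daily <- if (inherits(forecast, "coarse_cube")) aggregate_to_daily(forecast) else forecast
  stopifnot(inherits(daily, "temp_cube"))

  grid <- expand.grid(lat = model$lats, lon = model$lons)
  cgrid <- expand.grid(lat = daily$lats, lon = daily$lons)
  des <- idw_weights(cgrid$lat, cgrid$lon, grid$lat, grid$lon, model$k, model$p)
  cm <- cube_matrix(daily)

  n_cell <- nrow(grid)
  fine <- matrix(NA_real_, n_cell, ncol(cm))
  for (cell in seq_len(n_cell)) {
    j <- des$idx[cell, !is.na(des$idx[cell, ])]
    fine[cell, ] <- as.vector(des$w[cell, seq_along(j), drop = FALSE] %*% cm[j, , drop = FALSE])
  }
  months <- day_month(daily$days, daily$ref_year)
  nlat <- length(model$lats)
  for (mo in unique(months)) {
    sel <- months == mo
    a <- as.vector(model$slope[, , mo])
    b <- as.vector(model$intercept[, , mo])
    fine[, sel] <- fine[, sel, drop = FALSE] * a + b   # recycles by cell
  }
  temperature_cube(array(fine, c(nlat, length(model$lons), ncol(cm))),
                   model$lats, model$lons, daily$days, daily$ref_year)
}
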