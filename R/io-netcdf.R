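#' Write gridded objects to netCDF
#'
#' All gridded artifacts are exchanged as compressed netCDF-4 files with
#' CF-style conventions: dimensions `lat`, `lon` (cell-center degrees,
#' latitude stored north to south) and, where applicable, `time` (days
#' since 1 January of the reference year) or `month`. Temperature cubes
#' store a `tmean` variable in degrees C; forecast products store
#' `prediction`, `sd`, `pi_low`, `pi_high`, `anomaly` and `mask`;
#' downscaling models store `slope` and `intercept` per calendar month.
#'
#' @param x A [temperature_cube()], `forecast_product` or
#'   `downscaling_model`.
#' @param path Output file path.
#' @param compress Deflate level 0-9 (default 4). Compression matters:
#'   gridded forecast output is orders of magnitude smaller as compressed
#'   netCDF than as delimited text.
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path, compress = 4) {
  UseMethod("write_grid")
}

FILL <- 9.9692099683868690e+36  # netCDF default float fill

# ncvar_put() replaces NA with the fill value *in place*, mutating the
# caller's array; substitute into a local copy first.
nc_put <- function(nc, var, vals, missval = FILL) {
  vals[is.na(vals)] <- missval
  ncdf4::ncvar_put(nc, var, vals)
}

nc_coord_dims <- function(x) {
  list(
    lat = ncdf4::ncdim_def("lat", "degrees_north", as.double(x$lats)),
    lon = ncdf4::ncdim_def("lon", "degrees_east", as.double(x$lons))
  )
}

nc_put_common_atts <- function(nc, type) {
  ncdf4::ncatt_put(nc, 0, "phenocast_type", type)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.6")
  ncdf4::ncatt_put(nc, 0, "grid_order", "row-major north-to-south, cell-center coordinates")
}

#' @export
write_grid.temp_cube <- function(x, path, compress = 4) {
  dims <- nc_coord_dims(x)
  time_dim <- ncdf4::ncdim_def(
    "time", sprintf("days since %d-01-01", x$ref_year), as.double(x$days - 1L)
  )
  var <- ncdf4::ncvar_def("tmean", "degrees_C", list(dims$lat, dims$lon, time_dim),
                          missval = FILL, compression = compress)
  nc <- ncdf4::nc_create(path, list(var), force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  nc_put(nc, var, x$values)
  nc_put_common_atts(nc, "temp_cube")
  ncdf4::ncatt_put(nc, 0, "ref_year", x$ref_year)
  invisible(path)
}

#' @export
write_grid.forecast_product <- function(x, path, compress = 4) {
  dims <- nc_coord_dims(x)
  dl <- list(dims$lat, dims$lon)
  vars <- list(
    prediction = ncdf4::ncvar_def("prediction", "extended day of year", dl,
                                  missval = FILL, compression = compress),
    sd = ncdf4::ncvar_def("sd", "days", dl, missval = FILL, compression = compress),
    pi_low = ncdf4::ncvar_def("pi_low", "extended day of year", dl,
                              missval = FILL, compression = compress),
    pi_high = ncdf4::ncvar_def("pi_high", "extended day of year", dl,
                               missval = FILL, compression = compress),
    anomaly = ncdf4::ncvar_def("anomaly", "days", dl, missval = FILL,
                               compression = compress),
    mask = ncdf4::ncvar_def("mask", "boolean", dl, missval = -1L,
                            prec = "integer", compression = compress)
  )
  nc <- ncdf4::nc_create(path, vars, force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  for (v in c("prediction", "sd", "pi_low", "pi_high", "anomaly")) {
    nc_put(nc, vars[[v]], x[[v]])
  }
  nc_put(nc, vars$mask, x$mask * 1L, missval = -1L)
  nc_put_common_atts(nc, "forecast_product")
  ncdf4::ncatt_put(nc, 0, "species", x$species)
  ncdf4::ncatt_put(nc, 0, "phenophase", x$phenophase)
  ncdf4::ncatt_put(nc, 0, "issue_day", x$issue_day)
  ncdf4::ncatt_put(nc, 0, "ref_year", x$ref_year)
  ncdf4::ncatt_put(nc, 0, "model_version", x$model_version)
  invisible(path)
}

#' @export
write_grid.downscaling_model <- function(x, path, compress = 4) {
  dims <- nc_coord_dims(x)
  month_dim <- ncdf4::ncdim_def("month", "calendar month", 1:12)
  dl <- list(dims$lat, dims$lon, month_dim)
  vars <- list(
    slope = ncdf4::ncvar_def("slope", "unitless", dl, missval = FILL,
                             compression = compress),
    intercept = ncdf4::ncvar_def("intercept", "degrees_C", dl, missval = FILL,
                                 compression = compress)
  )
  nc <- ncdf4::nc_create(path, vars, force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  nc_put(nc, vars$slope, x$slope)
  nc_put(nc, vars$intercept, x$intercept)
  nc_put_common_atts(nc, "downscaling_model")
  ncdf4::ncatt_put(nc, 0, "idw_k", x$k)
  ncdf4::ncatt_put(nc, 0, "idw_p", x$p)
  invisible(path)
}

#' @export
write_grid.coarse_cube <- function(x, path, compress = 4) {
  dims <- nc_coord_dims(x)
  time_dim <- ncdf4::ncdim_def(
    "time", sprintf("days since %d-01-01", x$ref_year), as.double(x$times - 1)
  )
  var <- ncdf4::ncvar_def("tmean", "degrees_C", list(dims$lat, dims$lon, time_dim),
                          missval = FILL, compression = compress)
  nc <- ncdf4::nc_create(path, list(var), force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  nc_put(nc, var, x$values)
  nc_put_common_atts(nc, "coarse_cube")
  ncdf4::ncatt_put(nc, 0, "ref_year", x$ref_year)
  ncdf4::ncatt_put(nc, 0, "member_id", as.integer(x$member_id %||% NA_integer_))
  ncdf4::ncatt_put(nc, 0, "issue_day", as.integer(x$issue_day %||% NA_integer_))
  invisible(path)
}

#' Species range mask grid
#'
#' @param mask Logical matrix `[n_lat, n_lon]`, `TRUE` inside the range.
#' @param lats,lons Cell-center coordinates.
#' @return An object of class `range_mask`.
#' @export
range_mask <- function(mask, lats, lons) {
  stopifnot(is.logical(mask), nrow(mask) == length(lats), ncol(mask) == length(lons))
  structure(list(mask = mask, lats = lats, lons = lons), class = "range_mask")
}

#' @export
write_grid.range_mask <- function(x, path, compress = 4) {
  dims <- nc_coord_dims(x)
  var <- ncdf4::ncvar_def("mask", "boolean", list(dims$lat, dims$lon),
                          missval = -1L, prec = "integer", compression = compress)
  nc <- ncdf4::nc_create(path, list(var), force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, x$mask * 1L)
  nc_put_common_atts(nc, "range_mask")
  invisible(path)
}

#' Read a gridded object written by [write_grid()]
#'
#' The object type is recovered from the file's `phenocast_type` global
#' attribute; a file missing required variables fails with an error naming
#' them.
#'
#' @param path Path to a netCDF file produced by [write_grid()].
#' @return A [temperature_cube()], `forecast_product` or
#'   `downscaling_model`, matching what was written.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  nc <- tryCatch(ncdf4::nc_open(path),
                 error = function(e) abort(sprintf("cannot read '%s' as netCDF: %s",
                                                   path, conditionMessage(e))))
  on.exit(ncdf4::nc_close(nc))
  type <- ncdf4::ncatt_get(nc, 0, "phenocast_type")
  if (!type$hasatt) abort(sprintf("'%s' has no phenocast_type attribute.", path))

  need <- function(vars) {
    missing_v <- setdiff(vars, names(nc$var))
    if (length(missing_v)) {
      abort(sprintf("'%s' is missing required variable(s): %s",
                    path, paste(missing_v, collapse = ", ")))
    }
  }
  lats <- as.double(nc$dim$lat$vals)
  lons <- as.double(nc$dim$lon$vals)

  switch(type$value,
    temp_cube = {
      need("tmean")
      ref_year <- ncdf4::ncatt_get(nc, 0, "ref_year")$value
      days <- as.integer(round(nc$dim$time$vals)) + 1L
      vals <- ncdf4::ncvar_get(nc, "tmean", collapse_degen = FALSE)
      temperature_cube(vals, lats, lons, days, ref_year)
    },
    coarse_cube = {
      need("tmean")
      ref_year <- ncdf4::ncatt_get(nc, 0, "ref_year")$value
      times <- as.double(nc$dim$time$vals) + 1
      vals <- ncdf4::ncvar_get(nc, "tmean", collapse_degen = FALSE)
      coarse_cube(vals, lats, lons, times, ref_year,
                  member_id = ncdf4::ncatt_get(nc, 0, "member_id")$value,
                  issue_day = ncdf4::ncatt_get(nc, 0, "issue_day")$value)
    },
    range_mask = {
      need("mask")
      m <- ncdf4::ncvar_get(nc, "mask", collapse_degen = FALSE)
      range_mask(matrix(m == 1, length(lats), length(lons)), lats, lons)
    },
    forecast_product = {
      need(c("prediction", "sd", "pi_low", "pi_high", "anomaly", "mask"))
      g <- function(v) {
        m <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
        matrix(m, length(lats), length(lons))
      }
      structure(
        list(prediction = g("prediction"), sd = g("sd"), pi_low = g("pi_low"),
             pi_high = g("pi_high"), anomaly = g("anomaly"),
             mask = g("mask") == 1,
             species = ncdf4::ncatt_get(nc, 0, "species")$value,
             phenophase = ncdf4::ncatt_get(nc, 0, "phenophase")$value,
             issue_day = as.integer(ncdf4::ncatt_get(nc, 0, "issue_day")$value),
             ref_year = as.integer(ncdf4::ncatt_get(nc, 0, "ref_year")$value),
             lats = lats, lons = lons,
             model_version = ncdf4::ncatt_get(nc, 0, "model_version")$value),
        class = "forecast_product"
      )
    },
    downscaling_model = {
      need(c("slope", "intercept"))
      structure(
        list(lats = lats, lons = lons,
             slope = ncdf4::ncvar_get(nc, "slope", collapse_degen = FALSE),
             intercept = ncdf4::ncvar_get(nc, "intercept", collapse_degen = FALSE),
             k = ncdf4::ncatt_get(nc, 0, "idw_k")$value,
             p = ncdf4::ncatt_get(nc, 0, "idw_p")$value),
        class = "downscaling_model"
      )
    },
    abort(sprintf("unknown phenocast_type '%s' in '%s'.", type$value, path))
  )
}
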