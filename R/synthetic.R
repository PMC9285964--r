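#' Seeded synthetic fixtures
#'
#' Generators for every input the forecasting pipeline consumes —
#' temperature grids, status records and onset observations, coarse/fine
#' archive pairs with known affine maps, and multi-member forecast cubes —
#' with known ground truth, so the whole pipeline is testable offline.
#' Every generator derives its random stream from `(seed, purpose tag)`,
#' so identical seeds give identical outputs and adding a generator never
#' perturbs existing fixtures.
#'
#' @name synthetic-fixtures
NULL

# Deterministic sub-seed per (seed, tag); kept below 2^31 - 1.
tag_seed <- function(seed, tag) {
  chars <- utf8ToInt(tag)
  h <- sum(chars * seq_along(chars))
  as.integer((as.double(seed) %% 65536 * 48271 + h * 9973 + 1) %% 2147483647)
}

#' Synthetic daily temperature cube
#'
#' Cell temperatures follow a sinusoidal annual cycle with a latitudinal
#' lapse and optional daily noise:
#' `T(d) = mean - lapse * (lat - lat0) + amplitude * sin(2*pi*(d - phase)/365) + N(0, noise_sd)`
#' with `lat0` the grid's mean latitude. The default phase puts the warm
#' peak in mid July, so temperatures climb through a northern-hemisphere
#' spring.
#'
#' @param seed Integer seed.
#' @param nlat,nlon Grid dimensions.
#' @param days Extended day axis (consecutive integers).
#' @param ref_year Reference year anchoring day 1.
#' @param lat_range,lon_range Coordinate extents (lat north first).
#' @param mean_temp Annual mean at the central latitude, degrees C.
#' @param amplitude Seasonal half-range, degrees C.
#' @param lapse Cooling per degree of latitude northward, degrees C.
#' @param noise_sd Daily noise standard deviation, degrees C.
#' @param phase Day of the spring zero-crossing of the seasonal cycle.
#' @return A [temperature_cube()].
#' @export
synth_temperature_cube <- function(seed, nlat = 10, nlon = 10, days = -60:270,
                                   ref_year = 2019,
                                   lat_range = c(45, 35), lon_range = c(-100, -90),
                                   mean_temp = 12, amplitude = 10, lapse = 0.8,
                                   noise_sd = 0, phase = 105) {
  stopifnot(nlat >= 1, nlon >= 1)
  lats <- if (nlat == 1) lat_range[1] else seq(lat_range[1], lat_range[2], length.out = nlat)
  lons <- if (nlon == 1) lon_range[1] else seq(lon_range[1], lon_range[2], length.out = nlon)
  seasonal <- amplitude * sin(2 * pi * (days - phase) / 365)
  lat_term <- mean_temp - lapse * (lats - mean(lats))
  vals <- outer(lat_term, rep(1, nlon)) |> outer(seasonal, `+`)
  if (noise_sd > 0) {
    vals <- vals + withr::with_seed(
      tag_seed(seed, "temperature_cube"),
      array(rnorm(length(vals), 0, noise_sd), dim(vals))
    )
  }
  temperature_cube(vals, lats, lons, days, ref_year)
}

#' Synthetic onset observations and status records
#'
#' Draws observation sites at random grid cells, predicts each site's true
#' onset from a known phenology model, adds rounded Gaussian observation
#' noise, and constructs raw status records built to pass
#' [filter_status_records()] (a "no" 7 days before each onset "yes",
#' then the onset "yes"). Optionally injects known filter violations — a
#' plant with conflicting same-day records and a plant with two
#' yes-series in one year — for testing the filter.
#'
#' @param seed Integer seed.
#' @param model The true [phenology_model()].
#' @param cube A [temperature_cube()] spanning the event season.
#' @param n Number of sites/plants to draw.
#' @param noise_sd Observation noise standard deviation, days.
#' @param species,phenophase Labels for the generated group.
#' @param inject_violations Add the two violating plants (default FALSE).
#' @return A list: `observations` (onset tibble), `status_records`,
#'   `temps` (named list of [temperature_series()] by `site_id`), `sites`
#'   (site/cell lookup), `n_skipped` (sites where the true model predicts
#'   no event).
#' @export
synth_observations <- function(seed, model, cube, n = 50, noise_sd = 0,
                               species = "species_1", phenophase = "budburst",
                               inject_violations = FALSE) {
  nlat <- length(cube$lats); nlon <- length(cube$lons)
  n_cells <- nlat * nlon
  cells <- withr::with_seed(tag_seed(seed, "observation_sites"),
                            sample(n_cells, n, replace = n > n_cells))
  tm <- cube_matrix(cube)[cells, , drop = FALSE]
  true_day <- as.numeric(predict_days_matrix(tm, cube$days[1], model))
  keep <- !is.na(true_day)
  n_skipped <- sum(!keep)
  cells <- cells[keep]; true_day <- true_day[keep]; tm <- tm[keep, , drop = FALSE]

  noise <- if (noise_sd > 0) {
    withr::with_seed(tag_seed(seed, "observation_noise"),
                     round(rnorm(length(true_day), 0, noise_sd)))
  } else rep(0, length(true_day))
  onset <- as.integer(true_day + noise)

  i_lat <- ((cells - 1L) %% nlat) + 1L
  i_lon <- ((cells - 1L) %/% nlat) + 1L
  site_id <- sprintf("s%03d", seq_along(cells))
  obs <- tibble(
    plant_id = sprintf("p%03d", seq_along(cells)),
    site_id = site_id,
    latitude = cube$lats[i_lat],
    longitude = cube$lons[i_lon],
    species = species, phenophase = phenophase,
    year = cube$ref_year,
    onset_doy = onset
  )
  temps <- lapply(seq_along(cells), function(r) temperature_series(tm[r, ], cube$days[1]))
  names(temps) <- site_id

  status <- tibble(
    plant_id = rep(obs$plant_id, each = 2),
    site_id = rep(obs$site_id, each = 2),
    latitude = rep(obs$latitude, each = 2),
    longitude = rep(obs$longitude, each = 2),
    species = species, phenophase = phenophase,
    date = day_to_date(as.vector(rbind(obs$onset_doy - 7L, obs$onset_doy)), cube$ref_year),
    status = rep(c("no", "yes"), times = nrow(obs))
  )
  if (inject_violations) {
    base_date <- day_to_date(100, cube$ref_year)
    bad <- tibble(
      plant_id = c(rep("bad_conflict", 3), rep("bad_double", 6)),
      site_id = "s_bad", latitude = cube$lats[1], longitude = cube$lons[1],
      species = species, phenophase = phenophase,
      date = c(base_date - 7, base_date, base_date,                    # yes & no same day
               base_date - 7, base_date, base_date + 30,               # first series
               base_date + 60, base_date + 90, base_date + 97),        # second series
      status = c("no", "yes", "no",
                 "no", "yes", "yes", "no", "no", "yes")
    )
    status <- dplyr::bind_rows(status, bad)
  }
  list(observations = obs, status_records = status, temps = temps,
       sites = tibble(site_id = site_id, cell = cells, i_lat = i_lat, i_lon = i_lon),
       n_skipped = n_skipped)
}

#' Synthetic sub-daily coarse temperature cube
#'
#' The coarse-grid counterpart of [synth_temperature_cube()]: the same
#' smooth climate signal sampled at 6-h steps with a mean-zero diurnal
#' harmonic, so aggregating back to daily means recovers the daily signal
#' exactly.
#'
#' @inheritParams synth_temperature_cube
#' @param lats,lons Coarse cell-center coordinates (lats decreasing).
#' @param diurnal_amplitude Amplitude of the 24-h harmonic, degrees C.
#' @param member_id,issue_day Passed through to [coarse_cube()].
#' @return A [coarse_cube()] at 6-h steps.
#' @export
synth_coarse_cube <- function(seed, lats, lons, days, ref_year,
                              mean_temp = 12, amplitude = 10, lapse = 0.8,
                              noise_sd = 0, phase = 105, diurnal_amplitude = 4,
                              member_id = NA_integer_, issue_day = NA_integer_) {
  times <- as.vector(t(outer(days, c(0, 0.25, 0.5, 0.75), `+`)))
  seasonal <- amplitude * sin(2 * pi * (floor(times + 1e-9) - phase) / 365)
  diurnal <- diurnal_amplitude * sin(2 * pi * (times - floor(times + 1e-9)))
  lat_term <- mean_temp - lapse * (lats - mean(lats))
  vals <- outer(outer(lat_term, rep(1, length(lons))), seasonal + diurnal, `+`)
  if (noise_sd > 0) {
    vals <- vals + withr::with_seed(
      tag_seed(seed, "coarse_cube"),
      array(rnorm(length(vals), 0, noise_sd), dim(vals))
    )
  }
  coarse_cube(vals, lats, lons, times, ref_year, member_id, issue_day)
}

#' Fine-grid cube derived from a coarse cube through known affine maps
#'
#' Applies known per-cell monthly affine maps to the inverse-distance
#' interpolation of a coarse daily cube — the ground truth that a fitted
#' downscaling model must recover, and the generator of fine-grid "truth"
#' seasons in end-to-end experiments.
#'
#' @param coarse_daily A daily [temperature_cube()] on the coarse grid.
#' @param slope,intercept Truth arrays `[n_lat, n_lon, 12]`.
#' @param fine_lats,fine_lons Fine-grid coordinates.
#' @param k,p Inverse-distance parameters.
#' @param noise_sd Optional noise, degrees C.
#' @param seed Seed for the noise stream.
#' @return A fine-grid [temperature_cube()].
#' @export
synth_fine_from_coarse <- function(coarse_daily, slope, intercept,
                                   fine_lats, fine_lons, k = 4, p = 2,
                                   noise_sd = 0, seed = 1) {
  grid <- expand.grid(lat = fine_lats, lon = fine_lons)
  cgrid <- expand.grid(lat = coarse_daily$lats, lon = coarse_daily$lons)
  des <- idw_weights(cgrid$lat, cgrid$lon, grid$lat, grid$lon, k, p)
  cm <- cube_matrix(coarse_daily)
  fine <- matrix(NA_real_, nrow(grid), ncol(cm))
  for (cell in seq_len(nrow(grid))) {
    j <- des$idx[cell, !is.na(des$idx[cell, ])]
    fine[cell, ] <- as.vector(des$w[cell, seq_along(j), drop = FALSE] %*% cm[j, , drop = FALSE])
  }
  months <- day_month(coarse_daily$days, coarse_daily$ref_year)
  for (mo in unique(months)) {
    sel <- months == mo
    fine[, sel] <- fine[, sel, drop = FALSE] * as.vector(slope[, , mo]) +
      as.vector(intercept[, , mo])
  }
  if (noise_sd > 0) {
    fine <- fine + withr::with_seed(tag_seed(seed, "fine_noise"),
                                    matrix(rnorm(length(fine), 0, noise_sd), nrow(fine)))
  }
  temperature_cube(array(fine, c(length(fine_lats), length(fine_lons), ncol(cm))),
                   fine_lats, fine_lons, coarse_daily$days, coarse_daily$ref_year)
}

#' Synthetic coarse/fine archive pair with known affine maps
#'
#' Builds a multi-year coarse 6-h archive and the matching fine-grid daily
#' archive, where each fine cell and calendar month is a known affine map
#' of the inverse-distance-interpolated coarse daily signal — exactly the
#' relationship [build_downscaling_model()] estimates, so recovery can be
#' checked against ground truth.
#'
#' @param seed Integer seed.
#' @param fine_lats,fine_lons Fine-grid coordinates.
#' @param coarse_lats,coarse_lons Coarse-grid coordinates (defaults: a
#'   slightly wider 0.25-degree-style grid around the fine extent).
#' @param start_year First archive year.
#' @param years Number of archive years.
#' @param slope_range,intercept_range Uniform ranges the true per
#'   cell/month slopes and intercepts are drawn from.
#' @param noise_sd Noise added to the fine archive, degrees C.
#' @param k,p Inverse-distance parameters used to build the truth (match
#'   these when fitting).
#' @param ... Passed to [synth_coarse_cube()] (climate parameters).
#' @return A list: `coarse` (6-h [coarse_cube()]), `coarse_daily`, `fine`,
#'   `fine_true` (noise-free), `slope`, `intercept` (truth arrays
#'   `[lat, lon, 12]`).
#' @export
synth_coarse_fine_pair <- function(seed, fine_lats, fine_lons,
                                   coarse_lats = NULL, coarse_lons = NULL,
                                   start_year = 2015, years = 2,
                                   slope_range = c(0.8, 1.2),
                                   intercept_range = c(-2, 2),
                                   noise_sd = 0, k = 4, p = 2, ...) {
  if (is.null(coarse_lats)) {
    coarse_lats <- seq(max(fine_lats) + 0.25, min(fine_lats) - 0.25, by = -0.5)
  }
  if (is.null(coarse_lons)) {
    coarse_lons <- seq(min(fine_lons) - 0.25, max(fine_lons) + 0.25, by = 0.5)
  }
  n_days <- as.integer(as.Date(sprintf("%d-12-31", start_year + years - 1)) -
                         as.Date(sprintf("%d-01-01", start_year))) + 1L
  days <- seq_len(n_days)
  coarse <- synth_coarse_cube(seed, coarse_lats, coarse_lons, days, start_year, ...)
  coarse_daily <- aggregate_to_daily(coarse)

  nlat <- length(fine_lats); nlon <- length(fine_lons)
  maps <- withr::with_seed(tag_seed(seed, "affine_maps"), list(
    slope = array(runif(nlat * nlon * 12, slope_range[1], slope_range[2]),
                  c(nlat, nlon, 12)),
    intercept = array(runif(nlat * nlon * 12, intercept_range[1], intercept_range[2]),
                      c(nlat, nlon, 12))
  ))
  fine_true <- synth_fine_from_coarse(coarse_daily, maps$slope, maps$intercept,
                                      fine_lats, fine_lons, k, p)
  fine <- if (noise_sd > 0) {
    synth_fine_from_coarse(coarse_daily, maps$slope, maps$intercept,
                           fine_lats, fine_lons, k, p, noise_sd, seed)
  } else fine_true
  list(coarse = coarse, coarse_daily = coarse_daily, fine = fine,
       fine_true = fine_true, slope = maps$slope, intercept = maps$intercept)
}

#' Synthetic forecast ensemble members
#'
#' Perturbs a base coarse forecast cube into an ensemble: the first member
#' is the base itself; each further member adds a smooth perturbation
#' whose standard deviation grows with lead time from the issue day at
#' `spread_rate` degrees C per day. With `spread_rate = 0` all members are
#' identical.
#'
#' @param seed Integer seed.
#' @param base A [coarse_cube()] (the unperturbed forecast).
#' @param n Number of members (default 5).
#' @param issue_day Extended day index the forecast is issued; times before
#'   it are left unperturbed.
#' @param spread_rate Perturbation growth, degrees C per day of lead.
#' @param knot_spacing Days between perturbation knots (smoothness).
#' @return List of `n` [coarse_cube()] members.
#' @export
synth_climate_members <- function(seed, base, n = 5, issue_day,
                                  spread_rate = 0.02, knot_spacing = 15) {
  stopifnot(inherits(base, "coarse_cube"), n >= 1)
  members <- vector("list", n)
  members[[1]] <- base
  members[[1]]$member_id <- 1L
  members[[1]]$issue_day <- as.integer(issue_day)
  if (n == 1L || spread_rate == 0) {
    for (m in seq_len(n)[-1]) {
      members[[m]] <- members[[1]]
      members[[m]]$member_id <- as.integer(m)
    }
    return(members)
  }
  lead <- pmax(base$times - issue_day, 0)
  knots <- seq(min(base$times), max(base$times) + knot_spacing, by = knot_spacing)
  for (m in seq_len(n)[-1]) {
    z <- withr::with_seed(tag_seed(seed, paste0("member_", m)), rnorm(length(knots)))
    smooth <- approx(knots, z, xout = base$times, rule = 2)$y
    pert <- spread_rate * lead * smooth
    vals <- sweep(base$values, 3, pert, `+`)
    members[[m]] <- coarse_cube(vals, base$lats, base$lons, base$times,
                                base$ref_year, as.integer(m), as.integer(issue_day))
  }
  members
}

#' Synthetic species range mask
#'
#' @param nlat,nlon Grid dimensions.
#' @param type `"all"` (every cell in range), `"box"` (an interior
#'   rectangle), or `"checkerboard"`.
#' @return Logical matrix `[nlat, nlon]`.
#' @export
synth_range_mask <- function(nlat, nlon, type = c("all", "box", "checkerboard")) {
  type <- match.arg(type)
  switch(type,
    all = matrix(TRUE, nlat, nlon),
    box = {
      m <- matrix(FALSE, nlat, nlon)
      m[seq(max(1, floor(nlat / 4)), ceiling(3 * nlat / 4)),
        seq(max(1, floor(nlon / 4)), ceiling(3 * nlon / 4))] <- TRUE
      m
    },
    checkerboard = outer(seq_len(nlat), seq_len(nlon), function(i, j) (i + j) %% 2 == 0)
  )
}
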