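# Shared fixture builders. Everything is generated in code at test time;
# no data files.

const_series <- function(temp, n = 120, start_day = 1L) {
  temperature_series(rep(temp, n), start_day = start_day)
}

tt_model <- function(t1 = 1, T_base = 0, F_star = 100) {
  phenology_model("thermal_time", list(t1 = t1, T_base = T_base, F_star = F_star))
}

# A status-record row builder for filter tests.
status_row <- function(plant, day, status, species = "sp", phenophase = "budburst",
                       year = 2019) {
  tibble::tibble(
    plant_id = plant, site_id = paste0("site_", plant),
    latitude = 40, longitude = -100,
    species = species, phenophase = phenophase,
    date = day_to_date(day, year), status = status
  )
}

# The 12-record toy set: one clean series (3 records), one plant with
# conflicting same-day records (3), one plant with two yes-series in a
# 12-month window (6). Exactly one onset should survive.
toy_status_records <- function() {
  dplyr::bind_rows(
    status_row("clean", 80, "no"),
    status_row("clean", 95, "yes"),
    status_row("clean", 102, "yes"),
    status_row("conflict", 78, "no"),
    status_row("conflict", 90, "yes"),
    status_row("conflict", 90, "no"),
    status_row("double", 75, "no"),
    status_row("double", 82, "yes"),
    status_row("double", 110, "no"),
    status_row("double", 150, "no"),
    status_row("double", 160, "yes"),
    status_row("double", 170, "yes")
  )
}

# A small recoverable fitting problem: sites on a latitudinal gradient,
# onsets generated from a known thermal_time model.
make_recovery_problem <- function(seed, n = 40, noise_sd = 0, nlat = 8, nlon = 8,
                                  F_star = 300, T_base = 5, cube_noise = 1) {
  cube <- synth_temperature_cube(seed, nlat = nlat, nlon = nlon,
                                 noise_sd = cube_noise)
  truth <- phenology_model("thermal_time",
                           list(t1 = 1, T_base = T_base, F_star = F_star))
  so <- synth_observations(seed, truth, cube, n = n, noise_sd = noise_sd)
  c(so, list(cube = cube, truth = truth))
}

# In-memory pipeline config rooted at `wd`.
make_run_config <- function(wd, ...) {
  config <- list(
    seed = 42, ref_year = 2019, issue_day = 40, n_members = 3,
    min_obs = 30, min_horizon_days = 200, k_folds = 5,
    families = c("thermal_time", "linear"),
    fixed = list(thermal_time = list(t1 = 1)),
    synth = list(nlat = 5, nlon = 5, n_obs = 32, noise_sd = 2,
                 spread_rate = 0.02,
                 species = list(list(name = "species_a", phenophase = "budburst",
                                     family = "thermal_time",
                                     params = list(t1 = 1, T_base = 5, F_star = 250)))),
    paths = list(
      observations = file.path(wd, "observations.csv"),
      temperature_archive = file.path(wd, "observed.nc"),
      coarse_archive = file.path(wd, "coarse_archive.nc"),
      fine_archive = file.path(wd, "fine_archive.nc"),
      forecast_members = as.list(file.path(wd, sprintf("member_%d.nc", 1:3))),
      downscaling_model = file.path(wd, "downscaling.nc"),
      model_store = file.path(wd, "models"),
      publish_dir = file.path(wd, "forecasts"),
      verification = file.path(wd, "verification.csv")
    )
  )
  utils::modifyList(config, list(...))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

dir_file_hashes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(unname(tools::md5sum(files)), basename(files))
}
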