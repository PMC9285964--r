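#' Run configuration
#'
#' The pipeline commands share a single configuration, usually read from a
#' YAML file. Recognized fields (all paths relative to the config file's
#' directory unless absolute):
#'
#' * `seed`: integer driving every stochastic step.
#' * `ref_year`: the forecast season's event year.
#' * `issue_day`: extended day index the forecast is issued.
#' * `n_members`: nominal climate ensemble size (default 5).
#' * `observed_start`: `"1 Nov"` (extended day -60, default) or `"30 Nov"`
#'   (-31) — where the observed temperature series begins.
#' * `min_obs`: minimum observations per species-phenophase (default 30).
#' * `min_horizon_days`: days past issue a member forecast must reach
#'   before it is accepted (default 270, i.e. nine months).
#' * `k_folds`: stacking cross-validation folds (default 100).
#' * `families`: member families to fit (default all four).
#' * `fixed`: per-family lists of parameters to hold fixed during fitting.
#' * `paths`: `observations` (or `status_records`),
#'   `temperature_archive`, `coarse_archive`, `fine_archive`,
#'   `forecast_members` (list of netCDF paths), `fallback_members`,
#'   `downscaling_model`, `model_store`, `range_masks` (optional
#'   directory), `publish_dir`, `verification`.
#'
#' @param path YAML file path.
#' @param config A config list (from [read_run_config()] or built in
#'   code).
#' @return `read_run_config()` returns the validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  config <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  config$paths <- lapply(config$paths, function(p) {
    if (is.character(p)) {
      ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
    } else p
  })
  validate_run_config(config)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  defaults <- list(seed = 1L, n_members = 5L, observed_start = "1 Nov",
                   min_obs = 30L, min_horizon_days = 270L, k_folds = 100L,
                   families = pheno_families(), fixed = list())
  config <- modifyList(defaults, config)
  if (config$n_members < 1) abort("`n_members` must be >= 1.")
  if (!config$observed_start %in% c("1 Nov", "30 Nov")) {
    abort('`observed_start` must be "1 Nov" or "30 Nov".')
  }
  config
}

observed_start_day <- function(config) {
  if (config$observed_start == "30 Nov") -31L else -60L
}

pc_log <- function(step, ..., .level = "INFO") {
  kv <- list(...)
  msg <- paste(names(kv), unname(vapply(kv, as.character, character(1))),
               sep = "=", collapse = " ")
  inform(sprintf("[%s] %s step=%s %s", .level, format(Sys.time(), "%H:%M:%S"), step, msg))
}

# Nearest-cell temperature series for each site, keyed by site_id.
site_temperature_series <- function(cube, sites) {
  i <- vapply(sites$latitude, function(x) which.min(abs(cube$lats - x)), integer(1))
  j <- vapply(sites$longitude, function(x) which.min(abs(cube$lons - x)), integer(1))
  temps <- lapply(seq_len(nrow(sites)), function(r) cell_series(cube, i[r], j[r]))
  names(temps) <- as.character(sites$site_id)
  temps
}

model_file_name <- function(species, phenophase) {
  sprintf("%s__%s.json", gsub("[^A-Za-z0-9_-]", "_", species),
          gsub("[^A-Za-z0-9_-]", "_", phenophase))
}

#' Fit and store all species-phenophase models
#'
#' Reads onset observations (or raw status records, which are filtered
#' first), drops groups below the observation threshold, fits a stacked
#' ensemble and latitude baseline per group, and saves one JSON model
#' document per group plus a metadata index (`models.json`) into the model
#' store directory. Groups that fail to fit are logged and skipped; the
#' command fails only if every group fails.
#'
#' @param config A run configuration (see [read_run_config()]).
#' @return Invisibly, the metadata index as a tibble.
#' @export
cmd_fit <- function(config) {
  config <- validate_run_config(config)
  paths <- config$paths
  obs <- if (!is.null(paths$status_records)) {
    filter_status_records(read_status_records(paths$status_records))
  } else {
    read_observations(paths$observations)
  }
  obs <- require_min_observations(obs, config$min_obs)
  groups <- obs |> dplyr::distinct(.data$species, .data$phenophase)
  if (nrow(groups) == 0) abort("no species-phenophase group passes the observation threshold.")
  archive <- read_grid(paths$temperature_archive)
  dir.create(paths$model_store, recursive = TRUE, showWarnings = FALSE)

  index <- list()
  for (g in seq_len(nrow(groups))) {
    sp <- groups$species[g]; ph <- groups$phenophase[g]
    t0 <- Sys.time()
    res <- tryCatch({
      grp <- dplyr::filter(obs, .data$species == sp, .data$phenophase == ph)
      temps <- site_temperature_series(archive, dplyr::distinct(grp, .data$site_id,
                                                                .data$latitude, .data$longitude))
      ens <- fit_stacked_ensemble(grp, temps, members = config$families,
                                  k = config$k_folds, fixed = config$fixed,
                                  seed = tag_seed(config$seed, paste(sp, ph)))
      bl <- fit_latitude_baseline(grp)
      doc <- ensemble_to_document(ens, bl, sp, ph)
      fn <- model_file_name(sp, ph)
      save_model(doc, file.path(paths$model_store, fn))
      list(file = fn, n_obs = nrow(grp), oof_rmse = ens$cv$stacked_rmse)
    }, error = function(e) e)
    dur <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
    if (inherits(res, "error")) {
      pc_log("fit", species = sp, phenophase = ph, duration_s = dur,
             outcome = "skipped", reason = conditionMessage(res), .level = "WARN")
    } else {
      pc_log("fit", species = sp, phenophase = ph, duration_s = dur, outcome = "ok")
      index[[length(index) + 1]] <- c(list(species = sp, phenophase = ph), res)
    }
  }
  if (length(index) == 0) abort("all species-phenophase fits failed.")
  meta <- list(schema_version = MODEL_SCHEMA_VERSION,
               n_models = length(index), models = index)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             file.path(paths$model_store, "models.json"))
  pc_log("fit", outcome = "done", n_models = length(index))
  invisible(dplyr::bind_rows(lapply(index, as_tibble)))
}

#' Build and store the downscaling model
#'
#' Reads the coarse (sub-daily or daily) and fine daily archives, fits the
#' per-cell monthly asynchronous regressions, and writes the model as
#' netCDF.
#'
#' @param config A run configuration.
#' @return Invisibly, the `downscaling_model`.
#' @export
cmd_build_downscaling <- function(config) {
  config <- validate_run_config(config)
  coarse <- read_grid(config$paths$coarse_archive)
  if (inherits(coarse, "coarse_cube")) coarse <- aggregate_to_daily(coarse)
  fine <- read_grid(config$paths$fine_archive)
  t0 <- Sys.time()
  model <- build_downscaling_model(coarse, fine)
  write_grid(model, config$paths$downscaling_model)
  pc_log("build_downscaling",
         duration_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
         outcome = "ok")
  invisible(model)
}

# Accept a member if its daily span reaches min_horizon_days past issue;
# short members are replaced from the fallback list (mirroring the
# operational rule of discarding forecasts with insufficient series and
# obtaining a preceding one).
load_members <- function(config) {
  issue <- config$issue_day
  need_until <- issue + config$min_horizon_days
  ok <- list()
  fallbacks <- as.list(config$paths$fallback_members %||% list())
  for (p in config$paths$forecast_members) {
    cube <- read_grid(p)
    while (floor(max(cube$times)) < need_until) {
      pc_log("forecast", member = basename(p), outcome = "discarded",
             reason = "insufficient_series_length", .level = "WARN")
      if (length(fallbacks) == 0) { cube <- NULL; break }
      p <- fallbacks[[1]]; fallbacks <- fallbacks[-1]
      pc_log("forecast", member = basename(p), outcome = "fallback_used")
      cube <- read_grid(p)
    }
    if (!is.null(cube)) ok[[length(ok) + 1]] <- cube
  }
  if (length(ok) < 1) abort("no climate member with sufficient series length; aborting before publication.")
  ok
}

#' Run the gridded forecast and publish atomically
#'
#' Downscales each acceptable climate member, splices it with the observed
#' temperatures, runs every stored species-phenophase ensemble over the
#' grid, summarizes the member predictions into point estimate,
#' uncertainty, 95% interval and anomaly, crops to the species range, and
#' writes one compressed netCDF product per model. All products are
#' written to a staging directory and moved into the publish directory
#' only if every product succeeded, so a failure anywhere leaves the
#' previously published forecasts untouched.
#'
#' @param config A run configuration.
#' @return Invisibly, the published file names.
#' @export
cmd_forecast <- function(config) {
  config <- validate_run_config(config)
  paths <- config$paths
  issue <- as.integer(config$issue_day)

  index <- jsonlite::fromJSON(file.path(paths$model_store, "models.json"),
                              simplifyVector = FALSE)
  if (length(index$models) == 0) abort("model store is empty.")
  dsm <- read_grid(paths$downscaling_model)
  observed <- read_grid(paths$temperature_archive)
  start_day <- observed_start_day(config)
  keep <- observed$days >= start_day
  observed <- temperature_cube(observed$values[, , keep, drop = FALSE],
                               observed$lats, observed$lons,
                               observed$days[keep], observed$ref_year)

  raw_members <- load_members(config)
  members <- lapply(seq_along(raw_members), function(m) {
    fine <- apply_downscaling(raw_members[[m]], dsm)
    assemble_member(observed, fine, issue, member_id = m)
  })
  span <- range(members[[1]]$cube$days)

  staging <- paste0(paths$publish_dir, ".staging")
  unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  published <- character()
  result <- tryCatch({
    for (entry in index$models) {
      t0 <- Sys.time()
      doc <- load_model(file.path(paths$model_store, entry$file))
      loaded <- document_to_ensemble(doc)
      grids <- run_member_forecasts(members, loaded$ensemble)
      summ <- summarize_members(grids, span = span)
      summ$anomaly <- compute_anomaly(summ$point_estimate, loaded$baseline,
                                      observed$lats)
      mask <- read_species_mask(paths$range_masks, doc$species, doc$phenophase,
                                observed)
      product <- apply_range_mask(summ, mask, doc$species, doc$phenophase,
                                  issue, observed$lats, observed$lons,
                                  observed$ref_year)
      fn <- sprintf("%s__%s__day%03d.nc", gsub("[^A-Za-z0-9_-]", "_", doc$species),
                    gsub("[^A-Za-z0-9_-]", "_", doc$phenophase), issue)
      write_grid(product, file.path(staging, fn))
      published <- c(published, fn)
      pc_log("forecast", species = doc$species, phenophase = doc$phenophase,
             duration_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
             outcome = "staged")
    }
    TRUE
  }, error = function(e) e)

  if (inherits(result, "error")) {
    unlink(staging, recursive = TRUE)
    pc_log("forecast", outcome = "aborted", reason = conditionMessage(result),
           .level = "ERROR")
    abort(sprintf("forecast run failed; publish directory untouched: %s",
                  conditionMessage(result)))
  }
  dir.create(paths$publish_dir, recursive = TRUE, showWarnings = FALSE)
  for (fn in published) {
    file.rename(file.path(staging, fn), file.path(paths$publish_dir, fn))
  }
  unlink(staging, recursive = TRUE)
  pc_log("forecast", outcome = "published", n_products = length(published),
         issue_day = issue)
  invisible(published)
}

read_species_mask <- function(mask_dir, species, phenophase, grid) {
  if (is.null(mask_dir)) {
    return(matrix(TRUE, length(grid$lats), length(grid$lons)))
  }
  path <- file.path(mask_dir, sprintf("%s__%s.nc",
                                      gsub("[^A-Za-z0-9_-]", "_", species),
                                      gsub("[^A-Za-z0-9_-]", "_", phenophase)))
  if (!file.exists(path)) {
    return(matrix(TRUE, length(grid$lats), length(grid$lons)))
  }
  read_grid(path)$mask
}

#' Verify published forecasts against observed events
#'
#' Loads every product in the publish directory, scores them against the
#' observed events with [verify_forecasts()], and writes the verification
#' table as CSV.
#'
#' @param config A run configuration.
#' @param events_path CSV of observed events in the observation-table
#'   dialect (`onset_doy` is used as the observed day).
#' @param scope Passed to [verify_forecasts()].
#' @return The verification tibble, invisibly.
#' @export
cmd_verify <- function(config, events_path, scope = "forecastable") {
  config <- validate_run_config(config)
  files <- list.files(config$paths$publish_dir, pattern = "\\.nc$", full.names = TRUE)
  if (length(files) == 0) abort("no published forecast products to verify.")
  products <- lapply(files, read_grid)
  events <- read_observations(events_path) |>
    dplyr::rename(observed_doy = "onset_doy")
  vt <- verify_forecasts(products, events, scope = scope)
  if (!is.null(config$paths$verification)) {
    write_table(vt, config$paths$verification)
  }
  pc_log("verify", outcome = "ok", n_issue_dates = nrow(vt))
  invisible(vt)
}

#' Generate a complete synthetic scenario on disk
#'
#' Writes every input the pipeline commands need — onset observations, the
#' observed fine-grid temperature cube, coarse and fine downscaling
#' archives, climate forecast members, and range masks — for a fully
#' offline, reproducible demonstration run.
#'
#' @param config A run configuration; synthetic parameters may be set
#'   under `config$synth` (`nlat`, `nlon`, `n_obs`, `noise_sd`,
#'   `spread_rate`, `species`).
#' @return Invisibly, a list with the true models and written paths.
#' @export
cmd_synth <- function(config) {
  config <- validate_run_config(config)
  paths <- config$paths
  sy <- list(nlat = 8, nlon = 8, n_obs = 40, noise_sd = 2, spread_rate = 0.02,
             species = list(
               list(name = "species_a", phenophase = "budburst",
                    family = "thermal_time",
                    params = list(t1 = 1, T_base = 5, F_star = 250)),
               list(name = "species_b", phenophase = "flowers",
                    family = "thermal_time",
                    params = list(t1 = 1, T_base = 0, F_star = 600))
             ))
  # top-level replacement only: a user-supplied species list replaces the
  # default list outright (modifyList would merge them element-wise)
  for (nm in names(config$synth %||% list())) sy[[nm]] <- config$synth[[nm]]
  seed <- config$seed
  ref_year <- config$ref_year %||% 2019L
  fine_lats <- seq(45, 35, length.out = sy$nlat)
  fine_lons <- seq(-100, -90, length.out = sy$nlon)

  for (d in c(dirname(paths$observations), dirname(paths$temperature_archive),
              dirname(paths$forecast_members[[1]]), paths$model_store)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }

  # downscaling archives with known affine maps
  pair <- synth_coarse_fine_pair(seed, fine_lats, fine_lons,
                                 start_year = ref_year - 3, years = 2,
                                 noise_sd = 0)
  write_grid(pair$coarse, paths$coarse_archive)
  write_grid(pair$fine, paths$fine_archive)

  # season: coarse truth -> fine truth through the same maps
  season_days <- observed_start_day(config):(config$issue_day + config$min_horizon_days)
  coarse_season <- synth_coarse_cube(tag_seed(seed, "season"), pair$coarse$lats,
                                     pair$coarse$lons, season_days, ref_year)
  fine_truth <- synth_fine_from_coarse(aggregate_to_daily(coarse_season),
                                       pair$slope, pair$intercept,
                                       fine_lats, fine_lons)
  # the full-season fine truth doubles as the historical fitting archive;
  # cmd_forecast only uses its pre-issue days on the observed side of the
  # splice (the forecast side wins on overlap)
  write_grid(fine_truth, paths$temperature_archive)

  members <- synth_climate_members(seed, coarse_season, n = config$n_members,
                                   issue_day = config$issue_day,
                                   spread_rate = sy$spread_rate)
  for (m in seq_along(members)) write_grid(members[[m]], paths$forecast_members[[m]])

  truths <- list()
  all_obs <- list()
  for (spec in sy$species) {
    truth <- phenology_model(spec$family, spec$params)
    truths[[paste(spec$name, spec$phenophase, sep = "__")]] <- truth
    so <- synth_observations(tag_seed(seed, spec$name), truth, fine_truth,
                             n = sy$n_obs, noise_sd = sy$noise_sd,
                             species = spec$name, phenophase = spec$phenophase)
    all_obs[[length(all_obs) + 1]] <- so$observations
  }
  obs <- dplyr::bind_rows(all_obs)
  write_table(obs, paths$observations)
  pc_log("synth", outcome = "ok", n_obs = nrow(obs), n_members = length(members))
  invisible(list(truths = truths, observations = obs, paths = paths))
}
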