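#' Derive onset events from raw status records
#'
#' Status-based phenology monitoring asks an observer whether a phenophase
#' is present on a marked plant: the answer is "yes", "no", or "unsure".
#' This function reduces those raw records to one onset event per observed
#' yes-series, applying the quality rules used to build individual
#' phenometrics products:
#'
#' * "unsure" records are ignored;
#' * an onset is the first "yes" of a yes-series, kept only when the same
#'   plant and phenophase has a "no" record within the preceding 30 days;
#' * a plant is dropped entirely for a phenophase when it has conflicting
#'   records (a "yes" and a "no" on the same date) or more than one
#'   yes-series within any 12-month period.
#'
#' @param records A data frame of status records with columns `plant_id`,
#'   `site_id`, `latitude`, `longitude`, `species`, `phenophase`, `date`
#'   (a `Date` or parseable string), `status` (`"yes"`, `"no"`, `"unsure"`).
#' @param prior_no_days Maximum age, in days, of the prior "no" record that
#'   validates an onset (default 30).
#'
#' @return A tibble of onset events with columns `plant_id`, `site_id`,
#'   `latitude`, `longitude`, `species`, `phenophase`, `year`, `onset_doy`
#'   (extended day index within `year`). The result is independent of the
#'   input row order.
#' @examples
#' recs <- tibble::tibble(
#'   plant_id = 1, site_id = 1, latitude = 40, longitude = -100,
#'   species = "a", phenophase = "budburst",
#'   date = as.Date("2019-01-01") + c(79, 94),
#'   status = c("no", "yes")
#' )
#' filter_status_records(recs)
#' @export
filter_status_records <- function(records, prior_no_days = 30) {
  required <- c("plant_id", "site_id", "latitude", "longitude", "species",
                "phenophase", "date", "status")
  missing_c <- setdiff(required, names(records))
  if (length(missing_c)) {
    abort(paste0("`records` is missing column(s): ", paste(missing_c, collapse = ", ")))
  }
  records <- as_tibble(records)
  if (!inherits(records$date, "Date")) {
    parsed <- parse_dates(records$date)
    if (anyNA(parsed) && !all(is.na(records$date[is.na(parsed)]))) {
      bad <- which(is.na(parsed) & !is.na(records$date))
      abort(sprintf("unparseable date(s) in rows: %s",
                    paste(head(bad, 10), collapse = ", ")))
    }
    records$date <- parsed
  }
  bad_status <- setdiff(unique(records$status), c("yes", "no", "unsure"))
  if (length(bad_status)) {
    abort(paste0("invalid status value(s): ", paste(bad_status, collapse = ", ")))
  }

  records |>
    dplyr::filter(.data$status != "unsure") |>
    dplyr::arrange(.data$species, .data$phenophase, .data$plant_id, .data$date, .data$status) |>
    dplyr::group_by(.data$species, .data$phenophase, .data$plant_id) |>
    dplyr::group_modify(~ plant_onsets(.x, prior_no_days)) |>
    dplyr::ungroup() |>
    dplyr::select("plant_id", "site_id", "latitude", "longitude",
                  "species", "phenophase", "year", "onset_doy") |>
    dplyr::arrange(.data$species, .data$phenophase, .data$plant_id, .data$year)
}

# One plant x phenophase: apply the conflict / multiple-series / prior-no
# rules and emit zero or more onset rows.
plant_onsets <- function(df, prior_no_days) {
  empty <- df[0, c("site_id", "latitude", "longitude")] |>
    dplyr::mutate(year = integer(), onset_doy = integer())

  # conflicting status on the same date drops the plant outright
  conflict <- df |>
    dplyr::distinct(.data$date, .data$status) |>
    dplyr::count(.data$date) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) return(empty)

  df <- dplyr::distinct(df, .data$date, .keep_all = TRUE)
  yes <- df$status == "yes"
  if (!any(yes)) return(empty)

  # yes-series: maximal runs of "yes" uninterrupted by a "no";
  # the first observation of each run starts a series
  first_idx <- which(yes & !dplyr::lag(yes, default = FALSE))
  starts <- df$date[first_idx]

  # more than one yes-series within any 12-month window drops the plant
  if (length(starts) > 1) {
    gaps <- diff(as.numeric(starts))
    if (any(gaps <= 365)) return(empty)
  }

  no_dates <- df$date[df$status == "no"]
  keep <- vapply(starts, function(d) {
    any(no_dates < d & no_dates >= d - prior_no_days)
  }, logical(1))
  if (!any(keep)) return(empty)

  onset_dates <- starts[keep]
  yr <- as.integer(format(onset_dates, "%Y"))
  idx <- first_idx[keep]
  tibble(
    site_id = df$site_id[idx],
    latitude = df$latitude[idx],
    longitude = df$longitude[idx],
    year = yr,
    onset_doy = date_to_day(onset_dates, yr)
  )
}

#' Keep species-phenophase groups with enough observations
#'
#' Phenology models are only fit for species and phenophase combinations
#' with a minimum number of onset observations (default 30, boundary
#' inclusive).
#'
#' @param table An onset-event tibble as returned by
#'   [filter_status_records()].
#' @param n_min Minimum group size; groups with fewer rows are dropped.
#'
#' @return The filtered tibble.
#' @export
require_min_observations <- function(table, n_min = 30) {
  table |>
    dplyr::group_by(.data$species, .data$phenophase) |>
    dplyr::filter(dplyr::n() >= n_min) |>
    dplyr::ungroup()
}
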