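OBSERVATION_COLUMNS <- c("plant_id", "site_id", "latitude", "longitude",
                         "species", "phenophase", "year", "onset_doy")
STATUS_COLUMNS <- c("plant_id", "site_id", "latitude", "longitude",
                    "species", "phenophase", "date", "status")

#' Read onset observations from CSV
#'
#' The observation table dialect has the header
#' `plant_id, site_id, latitude, longitude, species, phenophase, year,
#' onset_doy` with `onset_doy` an extended day index within `year`. Rows
#' with unparseable numeric fields are dropped and collected into a
#' `rejects` attribute (with a warning) rather than failing the read.
#'
#' @param path CSV file path.
#' @return A tibble of onset events; the `rejects` attribute holds any
#'   dropped rows.
#' @export
read_observations <- function(path) {
  raw <- read_typed_csv(path, OBSERVATION_COLUMNS,
                        numeric_cols = c("latitude", "longitude", "year", "onset_doy"))
  raw$year <- as.integer(raw$year)
  raw$onset_doy <- as.integer(raw$onset_doy)
  raw
}

#' Read raw status records from CSV
#'
#' Header: `plant_id, site_id, latitude, longitude, species, phenophase,
#' date, status` with ISO dates and status `yes`/`no`/`unsure`. Rows with
#' bad dates or status values are dropped into the `rejects` attribute.
#'
#' @param path CSV file path.
#' @return A tibble of status records suitable for
#'   [filter_status_records()].
#' @export
read_status_records <- function(path) {
  raw <- read_typed_csv(path, STATUS_COLUMNS,
                        numeric_cols = c("latitude", "longitude"))
  dates <- parse_dates(raw$date)
  bad <- is.na(dates) | !(raw$status %in% c("yes", "no", "unsure"))
  if (any(bad)) {
    as_chr <- function(df) dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
    rej <- dplyr::bind_rows(as_chr(attr(raw, "rejects")), as_chr(raw[bad, ]))
    warn(sprintf("dropped %d status record(s) with bad dates or status values.", sum(bad)))
    raw <- raw[!bad, ]
    dates <- dates[!bad]
    attr(raw, "rejects") <- rej
  }
  raw$date <- dates
  raw
}

# Strict ISO (YYYY-MM-DD) date parsing: anything else becomes NA rather
# than raising or being guessed at.
parse_dates <- function(x) {
  as.Date(as.character(x), format = "%Y-%m-%d")
}

read_typed_csv <- function(path, columns, numeric_cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_c <- setdiff(columns, names(tbl))
  if (length(missing_c)) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  path, paste(missing_c, collapse = ", ")))
  }
  tbl <- tbl[columns]
  parsed <- tbl
  for (col in numeric_cols) parsed[[col]] <- suppressWarnings(as.numeric(tbl[[col]]))
  bad <- Reduce(`|`, lapply(numeric_cols, function(col) is.na(parsed[[col]]) & !is.na(tbl[[col]])))
  bad <- bad | Reduce(`|`, lapply(numeric_cols, function(col) is.na(tbl[[col]])))
  if (any(bad)) {
    warn(sprintf("dropped %d row(s) of '%s' with unparseable fields.", sum(bad), basename(path)))
  }
  out <- parsed[!bad, ]
  attr(out, "rejects") <- tbl[bad, ]
  out
}

#' Write a table to CSV
#'
#' Plain deterministic CSV output for observation tables, verification
#' tables and other tabular artifacts.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
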