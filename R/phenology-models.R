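#' Process-based phenology models
#'
#' Constructs a phenology model of one of four families. The first three are
#' thermal-forcing models: daily forcing units, derived from daily mean
#' temperature, accumulate from a start day `t1` until a requirement is met,
#' and the event is predicted on the first day the requirement is reached.
#' The fourth is a simple regression on mean spring temperature used as a
#' statistical member of the ensemble.
#'
#' Families and parameters (temperatures in degrees C, days on the extended
#' day axis):
#' \describe{
#'   \item{`thermal_time`}{growing-degree-day model. `t1`, `T_base`,
#'     `F_star`. Daily unit `max(0, T - T_base)`; event when the cumulative
#'     sum reaches `F_star`.}
#'   \item{`alternating`}{forcing accumulates as degree-days above 0 C, but
#'     the requirement relaxes with accumulated chill: on day `d` it is
#'     `a + b * exp(c * NCD_d)` where `NCD_d` counts days since `t1` with
#'     `T < chill_threshold` (default 5 C). `t1`, `a`, `b`, `c` (c < 0),
#'     `chill_threshold`.}
#'   \item{`uniforc`}{sigmoidal forcing response,
#'     `1 / (1 + exp(b_sig * (T - c_sig)))` with `b_sig < 0` so forcing
#'     increases with temperature. `t1`, `b_sig`, `c_sig`, `F_star`.}
#'   \item{`linear`}{`day = round(beta0 + beta1 * mean(T))` with the mean
#'     taken over the fixed window `[window_start, window_end]`.}
#' }
#'
#' @param family One of `"thermal_time"`, `"alternating"`, `"uniforc"`,
#'   `"linear"`.
#' @param params Named list of parameters for the family (see Details).
#'
#' @return An object of class `pheno_model`.
#' @examples
#' m <- phenology_model("thermal_time", list(t1 = 1, T_base = 5, F_star = 300))
#' s <- temperature_series(rep(10, 120), start_day = 1)
#' predict_event_day(s, m)
#' @export
phenology_model <- function(family, params) {
  family <- match.arg(family, pheno_families())
  params <- as.list(params)
  required <- pheno_param_names(family)
  if (family == "alternating" && is.null(params$chill_threshold)) {
    params$chill_threshold <- 5
  }
  missing_p <- setdiff(required, names(params))
  if (length(missing_p)) {
    abort(sprintf("family '%s' requires parameter(s): %s",
                  family, paste(missing_p, collapse = ", ")))
  }
  params <- params[required]
  vals <- unlist(params)
  if (any(!is.finite(vals))) abort("all model parameters must be finite.")
  if (!is.null(params$F_star) && params$F_star <= 0) abort("`F_star` must be > 0.")
  if (family == "uniforc" && params$b_sig >= 0) {
    abort("`b_sig` must be < 0 so forcing increases with temperature.")
  }
  if (family == "linear" && params$window_start >= params$window_end) {
    abort("`window_start` must be < `window_end`.")
  }
  if (family != "linear") params$t1 <- as.integer(round(params$t1))
  structure(list(family = family, params = params), class = "pheno_model")
}

pheno_families <- function() c("thermal_time", "alternating", "uniforc", "linear")

pheno_param_names <- function(family) {
  switch(family,
    thermal_time = c("t1", "T_base", "F_star"),
    alternating  = c("t1", "a", "b", "c", "chill_threshold"),
    uniforc      = c("t1", "b_sig", "c_sig", "F_star"),
    linear       = c("beta0", "beta1", "window_start", "window_end")
  )
}

#' @export
print.pheno_model <- function(x, ...) {
  p <- vapply(x$params, function(v) format(v, digits = 5), character(1))
  cat(sprintf("<pheno_model> %s(%s)\n", x$family,
              paste(names(p), p, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Daily and cumulative forcing units
#'
#' Evaluates the daily forcing response of a thermal-forcing model along a
#' temperature series and accumulates it from the model's start day `t1`.
#' Days before `t1` carry zero forcing.
#'
#' @param series A [temperature_series()] covering `t1` onward.
#' @param model A [phenology_model()] of a forcing family (not `linear`).
#'
#' @return A tibble with columns `day`, `unit` (the daily forcing unit) and
#'   `forcing` (cumulative forcing, non-decreasing).
#' @export
forcing_units <- function(series, model) {
  stopifnot(inherits(series, "temp_series"), inherits(model, "pheno_model"))
  if (model$family == "linear") abort("the linear family has no forcing units.")
  days <- series_days(series)
  t1 <- model$params$t1
  if (t1 < days[1]) {
    abort(sprintf("series starts at day %d but model t1 = %d: coverage error.", days[1], t1))
  }
  temps <- interpolate_gaps(series$values)
  unit <- daily_forcing(temps, model)
  unit[days < t1] <- 0
  tibble(day = days, unit = unit, forcing = cumsum(ifelse(is.na(unit), 0, unit)))
}

daily_forcing <- function(temps, model) {
  p <- model$params
  switch(model$family,
    thermal_time = pmax(temps - p$T_base, 0),
    alternating  = pmax(temps, 0),
    uniforc      = 1 / (1 + exp(p$b_sig * (temps - p$c_sig))),
    abort(sprintf("no forcing response for family '%s'.", model$family))
  )
}

#' Predict the event day for one temperature series
#'
#' Runs a phenology model over a daily temperature series and returns the
#' first extended day index on which the model's requirement is met, or
#' `NA` (no event) if it is never met within the series. Interior gaps of
#' up to 3 consecutive missing days are linearly interpolated; a longer gap
#' inside the accumulation window makes the prediction missing.
#'
#' @inheritParams forcing_units
#' @param model A [phenology_model()] of any family.
#'
#' @return Integer extended day index, or `NA` if no event occurs (or the
#'   series has an unresolvable gap).
#' @export
predict_event_day <- function(series, model) {
  stopifnot(inherits(series, "temp_series"), inherits(model, "pheno_model"))
  m <- matrix(series$values, nrow = 1)
  out <- predict_days_matrix(m, series$start_day, model)
  out[1]
}

# Vectorised event-day prediction: `tm` is an n_series x n_day matrix of
# daily temperatures whose first column is extended day `day0`. Returns an
# integer vector (NA = no event) with attribute "missing" marking rows whose
# prediction is undefined because of temperature gaps.
predict_days_matrix <- function(tm, day0, model) {
  n <- nrow(tm)
  days <- day0 + seq_len(ncol(tm)) - 1L
  p <- model$params

  if (anyNA(tm)) tm <- t(apply(tm, 1, interpolate_gaps))

  if (model$family == "linear") {
    keep <- days >= p$window_start & days <= p$window_end
    if (!any(keep)) {
      abort(sprintf("series (days %d..%d) does not cover the linear window [%d, %d].",
                    days[1], days[length(days)], p$window_start, p$window_end))
    }
    w <- tm[, keep, drop = FALSE]
    miss <- apply(w, 1, anyNA)
    pred <- as.integer(round(p$beta0 + p$beta1 * rowMeans(w)))
    pred[miss] <- NA_integer_
    # linear predictions outside the series span are clamped to it: the
    # model is only meaningful inside the days we have climate for
    pred[!miss] <- pmin(pmax(pred[!miss], days[1]), days[length(days)])
    return(structure(pred, missing = miss))
  }

  t1 <- p$t1
  if (t1 < days[1]) {
    abort(sprintf("series starts at day %d but model t1 = %d: coverage error.", days[1], t1))
  }
  keep <- days >= t1
  sub_days <- days[keep]
  if (length(sub_days) == 0L) {
    abort(sprintf("series ends at day %d, before model t1 = %d: coverage error.",
                  days[length(days)], t1))
  }
  # work days x series: columnwise cumulative sums vectorise in one pass,
  # and the crossing indicator is monotone in time for every forcing
  # family (cumulative forcing non-decreasing, requirement non-increasing),
  # so the first crossing is recovered from the crossing count alone
  sub <- t(tm[, keep, drop = FALSE])
  miss <- colSums(is.na(sub)) > 0L
  sub[is.na(sub)] <- 0  # masked below via `miss`

  unit <- switch(model$family,
    thermal_time = {
      u <- sub - p$T_base
      u[u < 0] <- 0
      u
    },
    alternating  = {
      u <- sub
      u[u < 0] <- 0
      u
    },
    uniforc      = 1 / (1 + exp(p$b_sig * (sub - p$c_sig)))
  )
  cum <- col_cumsum(unit)
  hit_count <- if (model$family == "alternating") {
    ncd <- col_cumsum((sub < p$chill_threshold) * 1)
    colSums(cum >= p$a + p$b * exp(p$c * ncd))
  } else {
    colSums(cum >= p$F_star)
  }
  pred <- sub_days[length(sub_days) + 1L - hit_count]
  pred[hit_count == 0L] <- NA_integer_
  pred[miss] <- NA_integer_
  structure(as.integer(pred), missing = miss)
}

# Columnwise cumulative sums of a matrix in one vectorised pass:
# cumsum() over the column-major vector, then subtract each column's
# carried-over predecessor total.
col_cumsum <- function(m) {
  d <- nrow(m); n <- ncol(m)
  v <- cumsum(m)
  if (n > 1L) {
    carry <- v[seq(d, by = d, length.out = n)]
    v <- v - rep(c(0, carry[-n]), each = d)
  }
  matrix(v, d, n)
}

#' Predict event days over a gridded temperature cube
#'
#' Applies a phenology model to every cell of a temperature cube,
#' producing the latitude x longitude matrix of predicted event days. Cells
#' whose temperature series cannot support a prediction (gaps longer than 3
#' days inside the window, or all-missing) are `NA` and flagged in the
#' `missing` attribute; cells where the requirement is simply never met are
#' `NA` without the flag.
#'
#' @param cube A [temperature_cube()] spanning the model's window.
#' @param model A [phenology_model()].
#'
#' @return Integer matrix `[n_lat, n_lon]` of extended day indices with a
#'   logical attribute `missing`.
#' @export
predict_grid <- function(cube, model) {
  stopifnot(inherits(cube, "temp_cube"), inherits(model, "pheno_model"))
  m <- cube_matrix(cube)
  pred <- predict_days_matrix(m, cube$days[1], model)
  out <- matrix_to_grid(as.integer(pred), cube)
  attr(out, "missing") <- matrix_to_grid(attr(pred, "missing"), cube)
  out
}

#' @export
predict.pheno_model <- function(object, newdata, ...) {
  if (inherits(newdata, "temp_series")) return(predict_event_day(newdata, object))
  if (inherits(newdata, "temp_cube")) return(predict_grid(newdata, object))
  abort("`newdata` must be a temp_series or temp_cube.")
}
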