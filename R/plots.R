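#' Map a forecast product layer
#'
#' @param object A `forecast_product`.
#' @param layer Which grid to map: `"prediction"`, `"anomaly"`, `"sd"` or
#'   `"interval_width"` (`pi_high - pi_low`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.forecast_product <- function(object, layer = c("prediction", "anomaly",
                                                        "sd", "interval_width"),
                                      ...) {
  layer <- match.arg(layer)
  df <- as_tibble(object) |>
    dplyr::mutate(interval_width = .data$pi_high - .data$pi_low)
  lab <- switch(layer,
    prediction = "predicted day of year",
    anomaly = "anomaly (days, negative = earlier)",
    sd = "forecast uncertainty (days)",
    interval_width = "95% interval width (days)"
  )
  fill_scale <- if (layer == "anomaly") {
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0, name = lab)
  } else {
    ggplot2::scale_fill_viridis_c(name = lab, na.value = "grey90")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    fill_scale +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s - %s", object$species, object$phenophase),
      subtitle = sprintf("issued day %d, %d", object$issue_day, object$ref_year),
      x = "longitude", y = "latitude"
    ) +
    ggplot2::theme_minimal()
}

#' Plot verification skill against issue date
#'
#' RMSE and mean forecast uncertainty as the season progresses: both
#' should shrink as the issue date approaches the events.
#'
#' @param verification A verification tibble from [verify_forecasts()].
#' @return A ggplot object.
#' @export
plot_verification <- function(verification) {
  df <- verification |>
    tidyr::pivot_longer(c("rmse", "mean_sd"), names_to = "metric",
                        values_to = "days") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric, rmse = "RMSE",
                                         mean_sd = "mean uncertainty (SD)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$issue_day, y = .data$days,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "forecast issue day", y = "days", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cumulative forcing for a model over a season
#'
#' @param series A [temperature_series()].
#' @param model A forcing-family [phenology_model()].
#' @return A ggplot object showing cumulative forcing and the predicted
#'   event day (if any).
#' @export
plot_forcing <- function(series, model) {
  df <- forcing_units(series, model)
  day <- predict_event_day(series, model)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$forcing)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "extended day of year", y = "cumulative forcing units") +
    ggplot2::theme_minimal()
  if (!is.na(day)) {
    p <- p + ggplot2::geom_vline(xintercept = day, linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
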