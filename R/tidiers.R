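#' Tidy methods for fitted phenology objects
#'
#' Broom-style summaries: `tidy()` returns one row per parameter or
#' member, `glance()` a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name phenocast-tidiers
NULL

#' @rdname phenocast-tidiers
#' @export
tidy.pheno_model <- function(x, ...) {
  tibble(family = x$family,
         term = names(x$params),
         estimate = as.numeric(unlist(x$params)))
}

#' @rdname phenocast-tidiers
#' @export
glance.pheno_model <- function(x, ...) {
  fit <- attr(x, "fit") %||% list()
  tibble(family = x$family,
         n_obs = fit$n_obs %||% NA_integer_,
         rmse = fit$rmse %||% NA_real_,
         seed = fit$seed %||% NA_integer_)
}

#' @rdname phenocast-tidiers
#' @export
tidy.stacked_ensemble <- function(x, ...) {
  oof_rmse <- if (!is.null(x$cv)) unname(x$cv$member_rmse) else NA_real_
  tibble(member = names(x$members),
         family = vapply(x$members, function(m) m$family, character(1)),
         weight = unname(x$weights),
         oof_rmse = oof_rmse)
}

#' @rdname phenocast-tidiers
#' @export
glance.stacked_ensemble <- function(x, ...) {
  tibble(n_members = length(x$members),
         k_folds = if (!is.null(x$cv)) x$cv$k else NA_integer_,
         stacked_oof_rmse = if (!is.null(x$cv)) x$cv$stacked_rmse else NA_real_,
         best_member_oof_rmse = if (!is.null(x$cv)) min(x$cv$member_rmse) else NA_real_)
}

#' @rdname phenocast-tidiers
#' @export
tidy.latitude_baseline <- function(x, ...) {
  tibble(term = c("(Intercept)", "latitude"),
         estimate = c(x$beta0, x$beta1),
         std.error = as.numeric(x$se))
}

#' @rdname phenocast-tidiers
#' @export
glance.latitude_baseline <- function(x, ...) {
  tibble(n_obs = x$n_obs, sigma = x$sigma)
}

#' @rdname phenocast-tidiers
#' @export
tidy.downscaling_model <- function(x, ...) {
  nlat <- length(x$lats); nlon <- length(x$lons)
  tibble(
    lat = rep(x$lats, times = nlon * 12),
    lon = rep(rep(x$lons, each = nlat), times = 12),
    month = rep(1:12, each = nlat * nlon),
    slope = as.vector(x$slope),
    intercept = as.vector(x$intercept)
  )
}
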