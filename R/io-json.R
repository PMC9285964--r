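MODEL_SCHEMA_VERSION <- "1.0"

#' Build a model document from a fitted ensemble
#'
#' A *model document* is the serializable description of one fitted
#' species-phenophase model: the four member models with their parameters
#' and fit metadata, the stacking weights, and the latitude baseline. It
#' is stored as text-based JSON so fitted models can be tracked, diffed
#' and version-controlled.
#'
#' @param ensemble A `stacked_ensemble`.
#' @param baseline A `latitude_baseline`.
#' @param species,phenophase Identity of the modeled group.
#' @return A `model_document` list with `schema_version`, `species`,
#'   `phenophase`, `members`, `weights` and `baseline`.
#' @export
ensemble_to_document <- function(ensemble, baseline, species, phenophase) {
  stopifnot(inherits(ensemble, "stacked_ensemble"), inherits(baseline, "latitude_baseline"))
  members <- lapply(names(ensemble$members), function(lab) {
    m <- ensemble$members[[lab]]
    fit <- attr(m, "fit") %||% list()
    list(
      label = lab,
      family = m$family,
      parameters = m$params,
      fit = list(n_obs = fit$n_obs %||% NA_integer_,
                 seed = fit$seed %||% NA_integer_,
                 objective = fit$rmse %||% NA_real_)
    )
  })
  structure(
    list(
      schema_version = MODEL_SCHEMA_VERSION,
      species = species,
      phenophase = phenophase,
      members = members,
      weights = as.list(ensemble$weights),
      baseline = list(beta0 = baseline$beta0, beta1 = baseline$beta1)
    ),
    class = "model_document"
  )
}

#' Reconstruct a usable ensemble from a model document
#'
#' @param doc A `model_document` from [ensemble_to_document()] or
#'   [load_model()].
#' @return A list with elements `ensemble` (a `stacked_ensemble` ready for
#'   prediction) and `baseline` (a `latitude_baseline`).
#' @export
document_to_ensemble <- function(doc) {
  validate_model_document(doc)
  members <- lapply(doc$members, function(m) phenology_model(m$family, m$parameters))
  names(members) <- vapply(doc$members, function(m) m$label %||% m$family, character(1))
  w <- unlist(doc$weights)
  ensemble <- structure(
    list(members = members, weights = w[names(members)], cv = NULL, seed = NA_integer_),
    class = "stacked_ensemble"
  )
  baseline <- structure(
    list(beta0 = doc$baseline$beta0, beta1 = doc$baseline$beta1,
         n_obs = NA_integer_, sigma = NA_real_, se = c(NA_real_, NA_real_)),
    class = "latitude_baseline"
  )
  list(ensemble = ensemble, baseline = baseline)
}

validate_model_document <- function(doc) {
  if (is.null(doc$schema_version)) abort("model document has no schema_version.")
  if (doc$schema_version != MODEL_SCHEMA_VERSION) {
    abort(sprintf("unsupported model document schema version '%s' (expected '%s').",
                  doc$schema_version, MODEL_SCHEMA_VERSION))
  }
  if (length(doc$members) < 1) abort("model document has no members.")
  for (m in doc$members) {
    if (!m$family %in% pheno_families()) {
      abort(sprintf("unknown model family '%s' in document.", m$family))
    }
    vals <- unlist(m$parameters)
    if (is.null(vals) || any(!is.finite(vals))) {
      abort(sprintf("member '%s' has missing or non-finite parameters.", m$family))
    }
  }
  w <- unlist(doc$weights)
  if (length(w) != length(doc$members)) abort("weights do not match members.")
  if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-6) {
    abort("ensemble weights must be non-negative and sum to 1 (within 1e-6).")
  }
  b <- unlist(doc$baseline)
  if (length(b) != 2 || any(!is.finite(b))) abort("baseline coefficients must be two finite numbers.")
  invisible(doc)
}

#' Save and load model documents as JSON
#'
#' Serialization is lossless (numbers written at full precision) and
#' deterministic: identical documents produce byte-identical files with a
#' stable key order, so stored models diff cleanly under version control.
#' Documents are validated on load; unknown families, non-finite
#' parameters, off-simplex weights and schema mismatches are rejected.
#'
#' @param doc A `model_document`.
#' @param path File path for the JSON document.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   validated `model_document`.
#' @export
save_model <- function(doc, path) {
  validate_model_document(doc)
  json <- jsonlite::toJSON(unclass(doc), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$weights <- lapply(doc$weights, as.numeric)
  doc$members <- lapply(doc$members, function(m) {
    m$fit <- list(n_obs = m$fit$n_obs %||% NA_integer_,
                  seed = m$fit$seed %||% NA_integer_,
                  objective = m$fit$objective %||% NA_real_)
    m
  })
  doc <- structure(doc, class = "model_document")
  validate_model_document(doc)
  doc
}
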