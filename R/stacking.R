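#' Simplex-constrained stacking weights
#'
#' Given a matrix of out-of-fold member predictions and the observed onset
#' days, finds the weights minimizing the RMSE of the weighted prediction
#' subject to non-negativity and summing to one. Because the weights sum
#' to one the problem reduces to minimizing `||E w||` over the simplex,
#' with `E` the member error matrix — a small quadratic program solved
#' exactly by active-set enumeration (the ensemble has only a handful of
#' members). Degenerate optima are resolved deterministically: among
#' weight vectors attaining the minimum, prefer the one with the smallest
#' weighted member mean-squared error (so hopeless members are excluded
#' rather than cancelled against each other), then the fewest members;
#' exact ties between interchangeable members (for example four identical
#' members) resolve to the uniform weight across them.
#'
#' @param pred Numeric matrix, observations x members, of out-of-fold
#'   predictions.
#' @param observed Numeric vector of observed onset days.
#' @return Numeric weight vector on the simplex (sums to 1, all >= 0).
#' @export
stacking_weights <- function(pred, observed) {
  pred <- as.matrix(pred)
  m <- ncol(pred)
  if (m == 1L) return(1)
  E <- pred - observed            # simplex weights make Pw - y == Ew
  if (m > 8L) return(stacking_weights_qp(E))

  sse <- function(w) drop(crossprod(E %*% w))
  member_mse <- colMeans(E^2)
  subsets <- unlist(lapply(seq_len(m), function(k) {
    utils::combn(m, k, simplify = FALSE)
  }), recursive = FALSE)
  candidates <- list()
  for (S in subsets) {
    wS <- simplex_lsq_subset(E[, S, drop = FALSE])
    if (is.null(wS) || any(wS < -1e-8)) next
    w <- numeric(m)
    w[S] <- pmax(wS, 0)
    w <- w / sum(w)
    candidates[[length(candidates) + 1]] <- list(
      w = w, sse = sse(w), penalty = sum(w * member_mse), size = length(S)
    )
  }
  best_sse <- min(vapply(candidates, `[[`, double(1), "sse"))
  tol <- 1e-9 * (best_sse + 1)
  optimal <- Filter(function(c) c$sse <= best_sse + tol, candidates)
  best_pen <- min(vapply(optimal, `[[`, double(1), "penalty"))
  optimal <- Filter(function(c) c$penalty <= best_pen + 1e-9 * (best_pen + 1), optimal)
  best_size <- min(vapply(optimal, `[[`, integer(1), "size"))
  optimal <- Filter(function(c) c$size == best_size, optimal)
  if (length(optimal) > 1) {
    # interchangeable members (identical error vectors): average the tied
    # vertices, which spreads weight uniformly across the equivalent members
    ws <- vapply(optimal, `[[`, double(m), "w")
    fits <- E %*% ws
    if (max(abs(fits - fits[, 1])) < 1e-9 * (max(abs(fits)) + 1)) {
      return(rowMeans(ws))
    }
  }
  optimal[[1]]$w
}

# Equality-constrained least squares on one support: min ||E_S w|| s.t.
# sum(w) = 1, via the KKT system (ridged if singular).
simplex_lsq_subset <- function(ES) {
  k <- ncol(ES)
  if (k == 1L) return(1)
  D <- crossprod(ES)
  K <- rbind(cbind(2 * D, 1), c(rep(1, k), 0))
  rhs <- c(rep(0, k), 1)
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    D <- D + diag(1e-8 * (mean(diag(D)) + 1), k)
    K <- rbind(cbind(2 * D, 1), c(rep(1, k), 0))
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
  }
  sol[seq_len(k)]
}

# Fallback for many members: ridged quadratic program on the error matrix.
stacking_weights_qp <- function(E) {
  m <- ncol(E)
  D <- crossprod(E)
  D <- D + diag(1e-8 * (mean(diag(D)) + 1), m)
  A <- cbind(rep(1, m), diag(m))
  sol <- quadprog::solve.QP(D, rep(0, m), A, bvec = c(1, rep(0, m)), meq = 1)
  w <- pmax(sol$solution, 0)
  w / sum(w)
}

#' Fit a stacked ensemble of phenology models
#'
#' Fits the four-model phenology ensemble for one species-phenophase
#' group. Ensemble weights are learned by stacking: observations are
#' partitioned into `k` random folds (default 100; reduced to n, i.e.
#' leave-one-out, when the group is smaller), every member is fit on each
#' training fold and predicted on its held-out fold, and the weights
#' minimizing held-out RMSE on the simplex are computed with
#' [stacking_weights()]. After the weights are determined each member is
#' refit once on the full data set.
#'
#' Members may be given as family names (fit by [fit_single_model()]) or as
#' ready-made [phenology_model()] objects, which are treated as fixed and
#' enter the cross-validation without refitting.
#'
#' @param obs Onset-event tibble for one species-phenophase group.
#' @param temps Named list of [temperature_series()] keyed by `site_id`.
#' @param members Character vector of family names, a list mixing family
#'   names and fixed `pheno_model` objects, or `NULL` for all four
#'   families.
#' @param k Number of cross-validation folds (default 100).
#' @param fixed Named list (by family) of lists of parameters to hold fixed
#'   during fitting, e.g. `list(thermal_time = list(t1 = 1))`.
#' @param control,cv_control Optimizer settings for the final full-data
#'   fits and the per-fold fits. The per-fold default is lighter: the fold
#'   fits only inform the weights, not the published parameters.
#' @param seed Integer seed; drives fold assignment and every member fit.
#'
#' @return An object of class `stacked_ensemble`: members (refit on all
#'   data), `weights` (named, on the simplex), and a `cv` list with the
#'   out-of-fold prediction matrix, per-member and stacked out-of-fold
#'   RMSE, `k`, and the fold assignment.
#' @export
fit_stacked_ensemble <- function(obs, temps, members = NULL, k = 100,
                                 fixed = list(),
                                 control = fit_control(),
                                 cv_control = fit_control(np = 25, itermax = 60, steptol = 15),
                                 seed = 1L) {
  if (is.null(members)) members <- pheno_families()
  if (is.character(members)) members <- as.list(members)
  labels <- vapply(seq_along(members), function(i) {
    m <- members[[i]]
    if (inherits(m, "pheno_model")) m$family else as.character(m)
  }, character(1))
  labels <- make.unique(labels)
  names(members) <- labels

  n <- nrow(obs)
  if (k > n) {
    warn(sprintf("k = %d folds exceeds n = %d observations; using leave-one-out (k = %d).", k, n, n))
    k <- n
  }
  mt <- obs_temperature_matrix(obs, temps)
  observed <- as.numeric(obs$onset_doy)
  folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))

  oof <- matrix(NA_real_, n, length(members), dimnames = list(NULL, labels))
  for (j in seq_along(members)) {
    mem <- members[[j]]
    if (inherits(mem, "pheno_model")) {
      pred <- predict_days_matrix(mt$tm, mt$day0, mem)
      oof[, j] <- as.numeric(pred)
    } else {
      for (f in seq_len(k)) {
        test <- folds == f
        fit_f <- fit_single_model(obs[!test, , drop = FALSE], temps, mem,
                                  fixed = fixed[[mem]] %||% list(),
                                  control = cv_control,
                                  seed = fold_seed(seed, j, f))
        pred <- predict_days_matrix(mt$tm[test, , drop = FALSE], mt$day0, fit_f)
        oof[test, j] <- as.numeric(pred)
      }
    }
  }
  # members that predict no event for a held-out observation are charged the
  # same finite penalty used during fitting, steering weight away from them
  oof_pen <- oof
  for (j in seq_len(ncol(oof_pen))) {
    bad <- is.na(oof_pen[, j])
    oof_pen[bad, j] <- observed[bad] + NO_EVENT_PENALTY
  }

  w <- stacking_weights(oof_pen, observed)
  names(w) <- labels

  refit <- lapply(labels, function(lab) {
    mem <- members[[lab]]
    if (inherits(mem, "pheno_model")) return(mem)
    fit_single_model(obs, temps, mem, fixed = fixed[[mem]] %||% list(),
                     control = control, seed = fold_seed(seed, match(lab, labels), 0L))
  })
  names(refit) <- labels

  member_rmse <- apply(oof_pen, 2, function(p) rmse(p - observed))
  stacked_rmse <- rmse(as.vector(oof_pen %*% w) - observed)

  structure(
    list(members = refit, weights = w,
         cv = list(oof = oof, k = k, folds = folds,
                   member_rmse = member_rmse, stacked_rmse = stacked_rmse),
         seed = seed),
    class = "stacked_ensemble"
  )
}

# Independent, reproducible sub-seed per (member, fold); kept below 2^31.
fold_seed <- function(seed, member, fold) {
  as.integer((as.double(seed) * 7919 + member * 104729 + fold * 131) %% 2147483647)
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat("<stacked_ensemble>\n")
  for (lab in names(x$members)) {
    cat(sprintf("  w = %.3f  ", x$weights[[lab]]))
    print(x$members[[lab]])
  }
  cat(sprintf("  out-of-fold RMSE %.2f d (k = %d)\n", x$cv$stacked_rmse, x$cv$k))
  invisible(x)
}

#' Predict with a stacked ensemble
#'
#' The ensemble prediction is the weighted mean of the member predicted
#' days, rounded to the nearest whole day, so the four sub-models act as a
#' single model. Members predicting no event at a cell are dropped and the
#' weights renormalized over the responding members; when the responding
#' weight falls below 0.5 the ensemble declines to forecast (returns `NA`),
#' so a low-confidence date is never published on the strength of a
#' minority of members.
#'
#' @param x A [temperature_series()] or [temperature_cube()].
#' @param ensemble A `stacked_ensemble` from [fit_stacked_ensemble()].
#' @return An integer day (series input) or integer matrix with a
#'   `missing` attribute (cube input).
#' @export
predict_ensemble <- function(x, ensemble) {
  stopifnot(inherits(ensemble, "stacked_ensemble"))
  if (inherits(x, "temp_series")) {
    preds <- vapply(ensemble$members, function(m) as.numeric(predict_event_day(x, m)), double(1))
    return(combine_members(matrix(preds, nrow = 1), ensemble$weights)[1])
  }
  if (!inherits(x, "temp_cube")) abort("`x` must be a temp_series or temp_cube.")
  grids <- lapply(ensemble$members, function(m) predict_grid(x, m))
  pm <- vapply(grids, as.numeric, double(length(grids[[1]])))
  out <- matrix_to_grid(combine_members(pm, ensemble$weights), x)
  miss <- Reduce(`&`, lapply(grids, attr, "missing"))
  attr(out, "missing") <- miss
  out
}

combine_members <- function(pm, w) {
  resp <- !is.na(pm)
  pm0 <- ifelse(resp, pm, 0)
  wsum <- resp %*% w
  est <- (pm0 %*% w) / wsum
  est[wsum < 0.5] <- NA_real_
  as.integer(round(est))
}

#' @export
predict.stacked_ensemble <- function(object, newdata, ...) {
  predict_ensemble(newdata, object)
}
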