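# Test-time inference: the shared latent is inferred from brain activity
# alone (the feature-view terms of the training-time latent update are
# dropped), then pushed through a feature view's loading to a predictive
# Gaussian over visual or semantic features.

#' Infer the latent posterior for test brain activity
#'
#' `Sz_test = beta_f (Wbar^(f)' Wbar^(f) + V^(f)) + I` and
#' `zbar_test = beta_f Sz_test^-1 Wbar^(f)' x_test`; only the brain view
#' contributes because test samples carry no feature observations.
#'
#' @param state a fitted `mvg_state`.
#' @param x_test brain-activity vector of length Df, or a Df x n matrix of
#'   test samples (standardized with the training statistics).
#' @return list with `mean` (Dz x n matrix) and `precision` (Dz x Dz, SPD).
#' @export
infer_test_latent <- function(state, x_test) {
  x_test <- as_matrix(x_test, "x_test")
  if (nrow(x_test) != state$dims[["brain"]])
    stop_invalid(sprintf("x_test has %d rows but the brain view has dimension %d",
                         nrow(x_test), state$dims[["brain"]]))
  W <- state$W[["brain"]]
  bf <- state$beta[["brain"]]
  prec <- bf * (crossprod(W) + diag(loading_var_diag(state, "brain"), state$Dz)) +
    diag(state$Dz)
  prec <- (prec + t(prec)) / 2
  mean <- bf * solve(prec, crossprod(W, x_test))
  list(mean = mean, precision = prec)
}

#' Predictive distribution of a feature view given test brain activity
#'
#' The predictive mean is `beta_f Wbar^(i) Sz_test^-1 Wbar^(f)' x_test` and
#' the covariance `Wbar^(i) Sz_test^-1 Wbar^(i)' + beta_i^-1 I`, obtained by
#' plugging the posterior-mean loadings into the latent predictive.
#'
#' @param state a fitted `mvg_state`.
#' @param x_test brain-activity vector or Df x n matrix.
#' @param view `"visual"` or `"semantic"`; must be part of the fitted model.
#' @return object of class `mvg_prediction`: `view`, `mean` (Di x n),
#'   `covariance` (Di x Di), `latent_mean`, `latent_precision`.
#' @export
predict_view <- function(state, x_test, view = c("visual", "semantic")) {
  view <- match.arg(view)
  if (!view %in% state$views)
    stop_config(sprintf("view '%s' was not part of the fitted model", view))
  lat <- infer_test_latent(state, x_test)
  Wi <- state$W[[view]]
  Szt_inv <- chol2inv(chol(lat$precision))
  mean <- Wi %*% lat$mean
  covariance <- Wi %*% Szt_inv %*% t(Wi) + diag(1 / state$beta[[view]],
                                                state$dims[[view]])
  covariance <- (covariance + t(covariance)) / 2
  structure(list(view = view, mean = mean, covariance = covariance,
                 latent_mean = lat$mean, latent_precision = lat$precision),
            class = "mvg_prediction")
}

#' Predict all feature views at once
#'
#' @inheritParams predict_view
#' @return named list of `mvg_prediction` objects, one per fitted feature view.
#' @export
predict_views <- function(state, x_test) {
  views <- setdiff(state$views, "brain")
  stats::setNames(lapply(views, function(v) predict_view(state, x_test, v)), views)
}

#' Ensemble prediction over random restarts
#'
#' Trains `n_models` models on the same data, differing only in the random
#' initialization (seeds `config$seed + 1, ..., config$seed + n_models`),
#' predicts with each, and returns the arithmetic mean of the predictive
#' means per view.  Averaging over restarts smooths out initialization noise
#' in the non-convex coordinate ascent.
#'
#' @param data a standardized [multiview_dataset()].
#' @param config an [model_config()]; its seed is the ensemble base seed.
#' @param x_test brain-activity vector or Df x n matrix (standardized).
#' @param n_models ensemble size T (default 100).
#' @return object of class `mvg_ensemble`: per-view averaged `mean`,
#'   `n_models`, and the `member_seeds` used.
#' @export
ensemble_predict <- function(data, config = model_config(), x_test,
                             n_models = 100) {
  n_models <- as.integer(n_models)
  if (is.na(n_models) || n_models < 1) stop_invalid("n_models must be >= 1")
  seeds <- config$seed + seq_len(n_models)
  sums <- NULL
  for (t in seq_len(n_models)) {
    cfg <- config
    cfg$seed <- seeds[t]
    preds <- tryCatch({
      st <- mvg_fit(data, cfg)
      lapply(predict_views(st, x_test), `[[`, "mean")
    }, error = function(e) {
      mvg_stop(sprintf("ensemble member with seed %d failed: %s",
                       seeds[t], conditionMessage(e)), "mvg_numeric_error")
    })
    sums <- if (is.null(sums)) preds
            else Map(`+`, sums, preds)
  }
  structure(list(mean = lapply(sums, `/`, n_models),
                 n_models = n_models, member_seeds = seeds),
            class = "mvg_ensemble")
}
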