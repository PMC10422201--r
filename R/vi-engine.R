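# Mean-field variational inference for the three-view linear-Gaussian
# latent-variable model with elementwise ARD priors on the loadings and
# imputation of unobserved brain-activity columns.
#
# Generative model, per sample n and view k in {brain, visual, semantic}:
#   z_n ~ N(0, I_Dz)
#   x_n^(k) | W^(k), z_n ~ N(W^(k) z_n, beta_k^-1 I)
#   W_ij^(k) ~ N(0, alpha_ij^(k)^-1),  alpha_ij^(k) ~ Gamma(mean a0, shape g0)
#   p(beta_k) propto 1/beta_k  (uninformative)
# Brain columns of the additional (unpaired) block are missing; their
# posterior means participate in every update and are refreshed each sweep.

#' Model configuration
#'
#' @param latent_dim dimension of the shared latent variable, or `"auto"`
#'   (the smallest feature dimension among the included views).
#' @param n_iterations number of full coordinate-ascent sweeps (default 10).
#' @param ard_prior_mean mean of the Gamma hyperprior on loading precisions
#'   (default 1).
#' @param ard_prior_shape shape of that hyperprior (default 0, i.e. flat).
#' @param ard_prior_scale the prior inverse-scale term entering the ARD
#'   update when `ard_prior_shape > 0` (default 0).
#' @param seed integer seed controlling the random initialization.
#' @param alpha_cap ceiling on posterior ARD precision means; pruned
#'   components are driven towards it (default 1e8).
#' @param beta_inv_floor floor on posterior noise variances (default 1e-12).
#' @param included_views subset of `c("brain","visual","semantic")`; must
#'   contain `"brain"`.  Two-view configurations give the Bayesian-CCA
#'   special cases.
#' @param rel_tol optional relative-change early-stopping tolerance on the
#'   reconstruction diagnostics; `NULL` (default) runs the fixed iteration
#'   count.
#' @param missing_variance when `TRUE`, the brain-view noise update adds the
#'   imputation variance `M * Df / beta_f` to the expected residual (the
#'   fully factorized expectation); the default `FALSE` treats imputed
#'   columns as fixed at their means, matching the printed update.
#' @return an object of class `mvg_config`.
#' @export
model_config <- function(latent_dim = "auto", n_iterations = 10,
                         ard_prior_mean = 1, ard_prior_shape = 0,
                         ard_prior_scale = 0, seed = 1L, alpha_cap = 1e8,
                         beta_inv_floor = 1e-12,
                         included_views = c("brain", "visual", "semantic"),
                         rel_tol = NULL, missing_variance = FALSE) {
  included_views <- order_views(match.arg(included_views, VIEW_ORDER,
                                          several.ok = TRUE))
  if (!"brain" %in% included_views)
    stop_config("included_views must contain 'brain'")
  if (!identical(latent_dim, "auto")) {
    latent_dim <- as.integer(latent_dim)
    if (is.na(latent_dim) || latent_dim < 1)
      stop_config("latent_dim must be a positive integer or 'auto'")
  }
  if (n_iterations < 1) stop_config("n_iterations must be >= 1")
  if (ard_prior_mean <= 0) stop_config("ard_prior_mean must be positive")
  if (ard_prior_shape < 0 || ard_prior_scale < 0)
    stop_config("ARD shape/scale terms must be non-negative")
  if (alpha_cap <= ard_prior_mean)
    stop_config("alpha_cap must exceed ard_prior_mean")
  structure(list(latent_dim = latent_dim, n_iterations = as.integer(n_iterations),
                 ard_prior_mean = ard_prior_mean,
                 ard_prior_shape = ard_prior_shape,
                 ard_prior_scale = ard_prior_scale,
                 seed = as.integer(seed), alpha_cap = alpha_cap,
                 beta_inv_floor = beta_inv_floor,
                 included_views = included_views, rel_tol = rel_tol,
                 missing_variance = isTRUE(missing_variance)),
            class = "mvg_config")
}

view_dims <- function(data, views) {
  d <- c(brain = nrow(data$brain), visual = nrow(data$visual),
         semantic = nrow(data$semantic))
  d[views]
}

resolve_latent_dim <- function(config, data) {
  dims <- view_dims(data, config$included_views)
  dz <- if (identical(config$latent_dim, "auto")) min(dims) else config$latent_dim
  if (dz > min(dims))
    stop_config(sprintf("latent_dim %d exceeds the smallest view dimension %d",
                        dz, min(dims)))
  as.integer(dz)
}

# Observed-or-imputed matrix for one view, Dk x (N+M).  Brain columns beyond
# the paired block come from the current posterior means of the missing data.
view_matrix <- function(state, data, view) {
  switch(view,
         brain = if (state$M > 0) cbind(data$brain, state$Xmiss) else data$brain,
         visual = if (state$M > 0) cbind(data$visual, data$add_visual) else data$visual,
         semantic = if (state$M > 0) cbind(data$semantic, data$add_semantic)
                    else data$semantic)
}

#' Initialize the variational state
#'
#' Latent means and missing brain columns are drawn i.i.d. standard normal
#' from their priors, loadings are drawn from the ARD prior at its prior
#' mean, noise precisions start at 1, and the latent/loading precisions start
#' at identity scale.  Given the same seed the state is bit-identical.
#'
#' @param data a standardized [multiview_dataset()].
#' @param config an [model_config()] object.
#' @return an object of class `mvg_state`.
#' @export
init_state <- function(data, config) {
  if (!inherits(data, "mv_dataset")) stop_invalid("data must be an mv_dataset")
  views <- config$included_views
  dims <- view_dims(data, views)
  dz <- resolve_latent_dim(config, data)
  n <- ncol(data$brain); m <- ncol(data$add_visual)
  set.seed(config$seed)
  Z <- matrix(stats::rnorm(dz * (n + m)), dz, n + m)
  Xmiss <- matrix(stats::rnorm(dims[["brain"]] * m), dims[["brain"]], m)
  a0 <- config$ard_prior_mean
  W <- W_prec <- alpha <- vector("list", length(views))
  names(W) <- names(W_prec) <- names(alpha) <- views
  for (k in views) {
    alpha[[k]] <- matrix(a0, dims[[k]], dz)
    W[[k]] <- matrix(stats::rnorm(dims[[k]] * dz, sd = sqrt(1 / a0)),
                     dims[[k]], dz)
    W_prec[[k]] <- matrix(1, dims[[k]], dz)
  }
  beta <- stats::setNames(rep(1, length(views)), views)
  gamma_beta <- stats::setNames(dims * (n + m) / 2, views)
  structure(list(views = views, dims = dims, Dz = dz, N = n, M = m,
                 W = W, W_prec = W_prec, alpha = alpha,
                 gamma_shape = 0.5 + config$ard_prior_shape,
                 beta = beta, gamma_beta = gamma_beta,
                 Z = Z, Sz = diag(dz), Sz_inv = diag(dz),
                 Xmiss = Xmiss, config = config, diagnostics = list()),
            class = "mvg_state")
}

#' @export
print.mvg_state <- function(x, ...) {
  cat(sprintf("Variational state: views {%s}, Dz=%d, N=%d, M=%d, %d sweep(s) logged\n",
              paste(x$views, collapse = ", "), x$Dz, x$N, x$M,
              length(x$diagnostics)))
  cat(sprintf("  noise precision means: %s\n",
              paste(sprintf("%s=%.4g", names(x$beta), x$beta), collapse = ", ")))
  invisible(x)
}

#' Coordinate-ascent update of one loading factor q(W^(k))
#'
#' Each element gets precision
#' `beta_k * (sum_n zbar_n(j)^2 + (N+M) * [Sz^-1]_jj) + alpha_ij`
#' and mean `beta_k / precision * sum_n x_n(i) zbar_n(j)`.
#'
#' @param state an `mvg_state`.
#' @param data the dataset the state was initialized on.
#' @param view one of the included views.
#' @return the updated state.
#' @export
update_w <- function(state, data, view) {
  X <- view_matrix(state, data, view)
  nm <- state$N + state$M
  s_j <- rowSums(state$Z^2) + nm * diag(state$Sz_inv)   # length Dz
  prec <- state$beta[[view]] * matrix(s_j, state$dims[[view]], state$Dz,
                                      byrow = TRUE) + state$alpha[[view]]
  cross <- X %*% t(state$Z)                              # Dk x Dz
  if (!all(is.finite(prec)) || !all(is.finite(cross)))
    stop_numeric(sprintf("non-finite intermediate in q(W) update for view %s", view))
  if (any(prec <= 0))
    stop_numeric(sprintf("non-positive loading precision in view %s", view))
  state$W_prec[[view]] <- prec
  state$W[[view]] <- state$beta[[view]] * cross / prec
  state
}

# Diagonal aggregation of elementwise loading variances: V^(k) has
# V_jj = sum_i 1/prec_ij (sum of posterior variances down column j).
loading_var_diag <- function(state, view) colSums(1 / state$W_prec[[view]])

#' Coordinate-ascent update of the shared latent factor q(Z)
#'
#' The common precision is
#' `Sz = sum_k beta_k (Wbar^(k)' Wbar^(k) + V^(k)) + I` with `V^(k)` the
#' diagonal aggregation of loading variances, and each latent mean is
#' `zbar_n = Sz^-1 sum_k beta_k Wbar^(k)' x_n^(k)`; brain columns of the
#' additional block enter through their current imputed means.
#'
#' @inheritParams update_w
#' @return the updated state.
#' @export
update_z <- function(state, data) {
  dz <- state$Dz
  Sz <- diag(dz)
  B <- matrix(0, dz, state$N + state$M)
  for (k in state$views) {
    W <- state$W[[k]]
    Sz <- Sz + state$beta[[k]] * (crossprod(W) + diag(loading_var_diag(state, k),
                                                      dz))
    B <- B + state$beta[[k]] * crossprod(W, view_matrix(state, data, k))
  }
  Sz <- (Sz + t(Sz)) / 2
  ch <- tryCatch(chol(Sz), error = function(e) NULL)
  if (is.null(ch))
    stop_numeric("latent precision matrix is not positive definite")
  state$Sz <- Sz
  state$Sz_inv <- chol2inv(ch)
  state$Z <- state$Sz_inv %*% B
  state
}

#' Refresh the imputed missing brain-activity means
#'
#' Each missing column becomes `Wbar^(brain) zbar_n` with per-coordinate
#' variance `1/beta_brain`; a no-op when the dataset has no additional block.
#'
#' @inheritParams update_w
#' @return the updated state.
#' @export
update_missing <- function(state) {
  if (state$M == 0) return(state)
  idx <- (state$N + 1):(state$N + state$M)
  state$Xmiss <- state$W[["brain"]] %*% state$Z[, idx, drop = FALSE]
  state$Xmiss_var <- 1 / state$beta[["brain"]]
  state
}

#' Coordinate-ascent update of the ARD precisions q(alpha^(k))
#'
#' Posterior shape is `1/2 + g0`; the posterior mean is
#' `shape / (Wbar_ij^2/2 + prec_ij^-1/2 + g0 * s0inv)`, clipped at
#' `alpha_cap` so pruned components stay finite.  With the default flat
#' hyperprior this reduces to `1 / (Wbar_ij^2 + prec_ij^-1)`.
#'
#' @inheritParams update_w
#' @param config the `mvg_config` used for the fit.
#' @return the updated state.
#' @export
update_alpha <- function(state, config = state$config) {
  g <- state$gamma_shape
  for (k in state$views) {
    denom <- state$W[[k]]^2 / 2 + 1 / state$W_prec[[k]] / 2 +
      config$ard_prior_shape * config$ard_prior_scale
    state$alpha[[k]] <- pmin(g / denom, config$alpha_cap)
  }
  state
}

#' Coordinate-ascent update of one noise precision q(beta_k)
#'
#' Posterior shape is `Dk (N+M) / 2`; the posterior mean inverse is the
#' expected squared reconstruction error
#' `sum_n ||x_n - Wbar zbar_n||^2 + Tr[V (sum_n zbar_n zbar_n' + (N+M) Sz^-1)]
#'  + (N+M) Tr[Sz^-1 Wbar' Wbar]`, divided by `Dk (N+M)` and floored at
#' `beta_inv_floor`.
#'
#' @inheritParams update_w
#' @return the updated state.
#' @export
update_beta <- function(state, data, view) {
  X <- view_matrix(state, data, view)
  nm <- state$N + state$M
  dk <- state$dims[[view]]
  if (dk * nm == 0) stop_config(sprintf("view %s is empty", view))
  err <- expected_recon_error(state, X, view)
  if (view == "brain" && state$M > 0 && isTRUE(state$config$missing_variance)) {
    # imputed columns are posterior means with per-coordinate variance
    # 1/beta_f; the factorized expectation of their residual carries that
    # variance, without which beta_f inflates as M grows
    err <- err + state$M * dk / state$beta[["brain"]]
  }
  beta_inv <- max(err / (dk * nm), state$config$beta_inv_floor)
  state$beta[[view]] <- 1 / beta_inv
  state
}

# Expected squared reconstruction error of one view under the current
# factorized posterior (the bracket of the beta update).
expected_recon_error <- function(state, X, view) {
  W <- state$W[[view]]
  nm <- state$N + state$M
  resid <- X - W %*% state$Z
  vdiag <- loading_var_diag(state, view)
  zz_diag <- rowSums(state$Z^2) + nm * diag(state$Sz_inv)
  sum(resid^2) + sum(vdiag * zz_diag) + nm * sum(state$Sz_inv * crossprod(W))
}

#' Fit the multi-view generative model
#'
#' Runs random initialization followed by `n_iterations` coordinate-ascent
#' sweeps in the fixed order W -> Z -> missing values -> ARD precisions ->
#' noise precisions, logging diagnostics after every sweep.
#'
#' @param data a standardized [multiview_dataset()].
#' @param config an [model_config()]; its `included_views` selects the full
#'   three-view model or a two-view Bayesian-CCA special case.
#' @return the final `mvg_state`, with one diagnostics record per sweep.
#' @seealso [fit_bcca()], [fit_mgm()] for the named special cases.
#' @export
mvg_fit <- function(data, config = model_config()) {
  state <- init_state(data, config)
  prev <- NULL
  for (it in seq_len(config$n_iterations)) {
    state <- tryCatch({
      for (k in state$views) state <- update_w(state, data, k)
      state <- update_z(state, data)
      state <- update_missing(state)
      state <- update_alpha(state, config)
      for (k in state$views) state <- update_beta(state, data, k)
      state
    }, mvg_error = function(e) {
      mvg_stop(sprintf("iteration %d: %s", it, conditionMessage(e)),
               class(e)[1])
    })
    d <- compute_diagnostics(state, data)
    state$diagnostics[[it]] <- d
    if (!is.null(config$rel_tol) && !is.null(prev)) {
      rel <- abs(d$recon_error - prev) / pmax(abs(prev), 1e-12)
      if (all(rel < config$rel_tol)) break
    }
    prev <- d$recon_error
  }
  state
}

#' Per-sweep diagnostics of a variational state
#'
#' @inheritParams update_w
#' @return list with `recon_error` (per-view expected squared reconstruction
#'   error under the current posterior), `beta` (noise precision means) and
#'   `n_pruned` (latent columns whose ARD precisions sit at the cap in every
#'   included view).
#' @export
compute_diagnostics <- function(state, data) {
  views <- state$views
  err <- stats::setNames(vapply(views, function(k)
    expected_recon_error(state, view_matrix(state, data, k), k), 0), views)
  cap <- state$config$alpha_cap
  at_cap <- Reduce(`&`, lapply(views, function(k)
    apply(state$alpha[[k]] >= cap, 2, all)))
  list(recon_error = err, beta = state$beta, n_pruned = sum(at_cap))
}

#' Named two-view and supervised-only special cases
#'
#' `fit_bcca()` fits the Bayesian-CCA reduction linking brain activity with a
#' single feature view on the paired block only (no additional samples).
#' `fit_mgm()` fits the three-view model without the semi-supervised block
#' (M = 0), i.e. the purely supervised multi-view generative model.
#' Both delegate to [mvg_fit()] so a two-view configuration of the general
#' engine and the dedicated entry point follow the same trajectory
#' bit-for-bit at equal seeds.
#'
#' @param data an [multiview_dataset()]; its additional block is dropped.
#' @param config an [model_config()]; `included_views` is overridden.
#' @param feature_view `"visual"` (BCCA-V) or `"semantic"` (BCCA-S).
#' @return an `mvg_state`.
#' @export
fit_bcca <- function(data, config = model_config(),
                     feature_view = c("visual", "semantic")) {
  feature_view <- match.arg(feature_view)
  config$included_views <- order_views(c("brain", feature_view))
  mvg_fit(drop_additional(data), config)
}

#' @rdname fit_bcca
#' @export
fit_mgm <- function(data, config = model_config()) {
  config$included_views <- c("brain", "visual", "semantic")
  mvg_fit(drop_additional(data), config)
}

#' Drop the additional (unpaired) block from a dataset
#'
#' @param data an [multiview_dataset()].
#' @return the dataset with M = 0.
#' @export
drop_additional <- function(data) {
  multiview_dataset(data$brain, data$visual, data$semantic, data$paired_labels,
                    zero_shot = data$zero_shot)
}

#' Principal angles between the column spans of two matrices
#'
#' @param a,b matrices with the same number of rows.
#' @return vector of angles in degrees, one per dimension of the smaller
#'   span, sorted increasingly.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as_matrix(a, "a")))
  qb <- qr.Q(qr(as_matrix(b, "b")))
  s <- svd(crossprod(qa, qb))$d
  sort(acos(pmin(pmax(s, -1), 1)) * 180 / pi)
}
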