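# Fitted-state checkpoints: a directory of delimited matrices plus a JSON
# scalar file, so checkpoints stay language-neutral and diff-able.

#' Save a fitted variational state to a directory
#'
#' @param state an `mvg_state` from [mvg_fit()].
#' @param dir output directory (created if needed).
#' @param stats optional per-view standardization statistics
#'   (from [standardize_bundle()]) stored alongside, so test data can be
#'   preprocessed consistently at prediction time.
#' @return `dir`, invisibly.
#' @export
save_state <- function(state, dir, stats = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_io(sprintf("cannot create directory %s", dir))
  for (k in state$views) {
    write_matrix_csv(state$W[[k]], file.path(dir, paste0("W_", k, ".csv")))
    write_matrix_csv(state$W_prec[[k]], file.path(dir, paste0("W_prec_", k, ".csv")))
    write_matrix_csv(state$alpha[[k]], file.path(dir, paste0("alpha_", k, ".csv")))
  }
  write_matrix_csv(state$Z, file.path(dir, "Z.csv"))
  write_matrix_csv(state$Sz, file.path(dir, "Sz.csv"))
  if (state$M > 0) write_matrix_csv(state$Xmiss, file.path(dir, "Xmiss.csv"))
  scalars <- list(views = state$views, dims = as.list(state$dims),
                  Dz = state$Dz, N = state$N, M = state$M,
                  beta = as.list(state$beta),
                  gamma_beta = as.list(state$gamma_beta),
                  gamma_shape = state$gamma_shape,
                  config = unclass(state$config))
  jsonlite::write_json(scalars, file.path(dir, "state.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  diag_path <- file.path(dir, "diagnostics.jsonl")
  writeLines(vapply(state$diagnostics, function(d)
    as.character(jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA)),
    ""), diag_path)
  if (!is.null(stats)) {
    st <- lapply(stats, function(s) list(mean = s$mean, sd = s$sd))
    jsonlite::write_json(st, file.path(dir, "standardization.json"),
                         digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Load a fitted variational state from a checkpoint directory
#'
#' @param dir directory written by [save_state()].
#' @return list with `state` (an `mvg_state`) and `stats` (standardization
#'   statistics, or `NULL` if none were stored).
#' @export
load_state <- function(dir) {
  spath <- file.path(dir, "state.json")
  if (!file.exists(spath)) stop_load(sprintf("no checkpoint in %s", dir))
  sc <- jsonlite::read_json(spath, simplifyVector = TRUE)
  views <- sc$views
  rd <- function(f) read_matrix_csv(file.path(dir, f))
  W <- W_prec <- alpha <- stats::setNames(vector("list", length(views)), views)
  for (k in views) {
    W[[k]] <- rd(paste0("W_", k, ".csv"))
    W_prec[[k]] <- rd(paste0("W_prec_", k, ".csv"))
    alpha[[k]] <- rd(paste0("alpha_", k, ".csv"))
  }
  Sz <- rd("Sz.csv")
  cfg <- sc$config
  config <- model_config(latent_dim = if (identical(cfg$latent_dim, "auto"))
    "auto" else cfg$latent_dim,
    n_iterations = cfg$n_iterations, ard_prior_mean = cfg$ard_prior_mean,
    ard_prior_shape = cfg$ard_prior_shape, ard_prior_scale = cfg$ard_prior_scale,
    seed = cfg$seed, alpha_cap = cfg$alpha_cap,
    beta_inv_floor = cfg$beta_inv_floor, included_views = cfg$included_views)
  state <- structure(list(views = views,
                          dims = unlist(sc$dims)[views], Dz = sc$Dz,
                          N = sc$N, M = sc$M, W = W, W_prec = W_prec,
                          alpha = alpha, gamma_shape = sc$gamma_shape,
                          beta = unlist(sc$beta)[views],
                          gamma_beta = unlist(sc$gamma_beta)[views],
                          Z = rd("Z.csv"), Sz = Sz, Sz_inv = chol2inv(chol(Sz)),
                          Xmiss = if (sc$M > 0) rd("Xmiss.csv")
                                  else matrix(0, unlist(sc$dims)[["brain"]], 0),
                          config = config, diagnostics = list()),
                     class = "mvg_state")
  stats <- NULL
  stpath <- file.path(dir, "standardization.json")
  if (file.exists(stpath)) {
    raw <- jsonlite::read_json(stpath, simplifyVector = TRUE)
    stats <- lapply(raw, function(s)
      structure(list(mean = s$mean, sd = s$sd, zero_var = s$sd == 0),
                class = "mv_standardization"))
  }
  list(state = state, stats = stats)
}
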