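# Sampling from the assumed generative process: three views driven by a
# shared latent variable with category-clustered latents, plus a zero-shot
# split (target categories have unpaired visual/semantic samples and test
# brain activity, but no paired training samples).

#' Sample ground-truth parameters for a synthetic decoding problem
#'
#' Loadings are drawn standard normal with a column sparsity mask applied
#' (masked latent components load on no view, giving ARD something to
#' prune).  Each category gets a latent prototype; source-category
#' prototypes are confined to a compact region, displaced along the first
#' active latent axis by `prototype_shift` and spread only `source_spread`
#' around that centre, while target and candidate-only prototypes spread
#' with unit scale.  Paired training data therefore under-explore the
#' latent directions on which target categories differ - the projection
#' domain shift is reproducible synthetically.  Noise precisions are set so
#' each view's mean per-coordinate signal variance exceeds its noise
#' variance by `snr`.
#'
#' @param dims named integer vector with entries `brain`, `visual`,
#'   `semantic` (feature dimensions per view).
#' @param latent_dim dimension of the shared latent variable.
#' @param n_source,n_target,n_distractor numbers of source, target and
#'   candidate-only categories (distractors enlarge the candidate set
#'   without appearing in any data block).
#' @param active_columns logical mask of length `latent_dim`; `FALSE`
#'   columns are zeroed in every view's loading.
#' @param snr per-view ratio of mean signal variance to noise variance.
#' @param tau within-category latent spread (latents are
#'   `prototype + tau * noise`).
#' @param prototype_shift displacement of source prototypes relative to
#'   target prototypes in latent space.
#' @param source_spread scale of source-prototype variation around the
#'   shifted centre (1 = same spread as targets; small values emulate a
#'   narrow source domain).
#' @param seed integer seed of the truth stream.
#' @return an object of class `mvg_truth` with true loadings `W`, noise
#'   precisions `beta`, prototypes (latent_dim x categories), category role
#'   lists, and the generating options.
#' @export
sample_ground_truth <- function(dims = c(brain = 60L, visual = 40L, semantic = 20L),
                                latent_dim = 5, n_source = 20, n_target = 8,
                                n_distractor = 50,
                                active_columns = rep(TRUE, latent_dim),
                                snr = 1, tau = 0.25, prototype_shift = 2,
                                source_spread = 0.25, seed = 1L) {
  if (!all(VIEW_ORDER %in% names(dims))) stop_config("dims must name all three views")
  dims <- vapply(dims[VIEW_ORDER], as.integer, 1L)
  if (any(dims < 1) || latent_dim < 1) stop_config("dims must be positive")
  if (length(active_columns) != latent_dim)
    stop_config("active_columns mask must have length latent_dim")
  if (!any(active_columns)) stop_config("at least one latent column must be active")
  if (snr <= 0) stop_config("snr must be positive")
  if (tau < 0) stop_config("tau must be non-negative")
  if (n_target < 1 || n_source < 1) stop_config("need source and target categories")
  set.seed(as.integer(seed))
  W <- lapply(dims, function(d) {
    w <- matrix(stats::rnorm(d * latent_dim), d, latent_dim)
    w[, !active_columns] <- 0
    w
  })
  if (source_spread <= 0) stop_config("source_spread must be positive")
  n_cat <- n_source + n_target + n_distractor
  prototypes <- matrix(stats::rnorm(latent_dim * n_cat), latent_dim, n_cat)
  shift_dir <- rep(0, latent_dim)
  shift_dir[which(active_columns)[1]] <- 1
  prototypes[, seq_len(n_source)] <-
    source_spread * prototypes[, seq_len(n_source)] + prototype_shift * shift_dir
  names_all <- c(sprintf("src%03d", seq_len(n_source)),
                 sprintf("tgt%03d", seq_len(n_target)),
                 if (n_distractor > 0) sprintf("cnd%03d", seq_len(n_distractor)))
  colnames(prototypes) <- names_all
  # latent marginal variance per coordinate is Var(prototype) + tau^2;
  # noise variance per view = mean signal variance / snr
  lat_var <- 1 + tau^2
  beta <- vapply(VIEW_ORDER, function(k) {
    signal_var <- lat_var * mean(rowSums(W[[k]]^2))
    snr / signal_var
  }, 0)
  structure(list(W = W, beta = beta, prototypes = prototypes,
                 active_columns = active_columns,
                 source = names_all[seq_len(n_source)],
                 target = names_all[n_source + seq_len(n_target)],
                 distractor = if (n_distractor > 0)
                   names_all[n_source + n_target + seq_len(n_distractor)]
                 else character(0),
                 latent_dim = latent_dim, dims = dims, snr = snr, tau = tau,
                 prototype_shift = prototype_shift, source_spread = source_spread,
                 seed = as.integer(seed)),
            class = "mvg_truth")
}

# one view sample block: W z + noise
gen_view <- function(W, Z, beta) {
  W %*% Z + matrix(stats::rnorm(nrow(W) * ncol(Z), sd = sqrt(1 / beta)),
                   nrow(W), ncol(Z))
}

# latents for a block of category labels
gen_latents <- function(truth, labels) {
  Z <- truth$prototypes[, labels, drop = FALSE]
  Z + truth$tau * matrix(stats::rnorm(length(Z)), nrow(Z), ncol(Z))
}

#' Sample a full zero-shot benchmark dataset from ground truth
#'
#' The paired block covers the source categories with all three views; the
#' additional block covers the target categories with visual and semantic
#' features only (their true brain activity is generated but withheld, for
#' imputation scoring); the test block is target-category brain activity.
#' Candidate vectors are the noiseless per-category prototypes
#' `W_true^(view) prototype_c` over all categories.
#'
#' Randomness is split into two streams: the paired/additional data stream
#' uses `seed`, the test stream `seed + 1`, so test draws do not perturb the
#' training data when test sizes change.
#'
#' @param truth an [sample_ground_truth()] object.
#' @param n_per_source samples per source category in the paired block.
#' @param m_add_per_target additional (unpaired) samples per target
#'   category; 0 gives the purely supervised setting.
#' @param n_test_per_target test samples per target category.
#' @param seed integer seed of the data stream.
#' @return list of class `mvg_benchmark`: `dataset` ([multiview_dataset()]),
#'   `test` ([test_set()]), `candidates` ([candidate_set()]), `hidden`
#'   (withheld truths: `add_brain`, `test_visual`, `test_semantic`), and the
#'   `truth` object.
#' @export
sample_dataset <- function(truth, n_per_source = 8, m_add_per_target = 5,
                           n_test_per_target = 2, seed = 2L) {
  if (!inherits(truth, "mvg_truth")) stop_invalid("truth must be an mvg_truth")
  if (n_per_source < 1 || n_test_per_target < 1)
    stop_config("paired and test blocks need at least one sample per category")
  if (m_add_per_target < 0) stop_config("m_add_per_target must be >= 0")
  if (length(truth$target) == 0) stop_config("target category set is empty")
  set.seed(as.integer(seed))
  paired_labels <- rep(truth$source, each = n_per_source)
  Zp <- gen_latents(truth, paired_labels)
  brain <- gen_view(truth$W$brain, Zp, truth$beta[["brain"]])
  visual <- gen_view(truth$W$visual, Zp, truth$beta[["visual"]])
  semantic <- gen_view(truth$W$semantic, Zp, truth$beta[["semantic"]])
  if (m_add_per_target > 0) {
    add_labels <- rep(truth$target, each = m_add_per_target)
    Za <- gen_latents(truth, add_labels)
    add_visual <- gen_view(truth$W$visual, Za, truth$beta[["visual"]])
    add_semantic <- gen_view(truth$W$semantic, Za, truth$beta[["semantic"]])
    add_brain <- gen_view(truth$W$brain, Za, truth$beta[["brain"]])
  } else {
    add_labels <- character(0)
    add_visual <- add_semantic <- add_brain <- NULL
  }
  dataset <- multiview_dataset(brain, visual, semantic, paired_labels,
                               add_visual, add_semantic, add_labels,
                               zero_shot = TRUE)
  set.seed(as.integer(seed) + 1L)
  test_labels <- rep(truth$target, each = n_test_per_target)
  Zt <- gen_latents(truth, test_labels)
  test_brain <- gen_view(truth$W$brain, Zt, truth$beta[["brain"]])
  test_visual <- truth$W$visual %*% Zt
  test_semantic <- truth$W$semantic %*% Zt
  cand <- candidate_set(colnames(truth$prototypes),
                        truth$W$visual %*% truth$prototypes,
                        truth$W$semantic %*% truth$prototypes)
  test <- test_set(test_brain, test_labels, cand)
  structure(list(dataset = dataset, test = test, candidates = cand,
                 hidden = list(add_brain = add_brain,
                               test_visual = test_visual,
                               test_semantic = test_semantic,
                               test_latents = Zt),
                 truth = truth, seed = as.integer(seed)),
            class = "mvg_benchmark")
}

#' Write a ready-to-run zero-shot benchmark bundle to disk
#'
#' Samples ground truth (truth stream `seed`) and data (data stream
#' `seed + 1`, test stream `seed + 2`), then writes manifests for the
#' dataset, test set and candidate set, the withheld truths for scoring,
#' and a top-level `benchmark.json` recording the full configuration and
#' seed so the bundle reruns identically.
#'
#' @param dir output directory.
#' @param seed master seed; all streams derive from it.
#' @param ... options forwarded to [sample_ground_truth()] and
#'   [sample_dataset()] (matched by name).
#' @return path of the top-level manifest, invisibly.
#' @export
make_benchmark <- function(dir, seed = 1L, ...) {
  opts <- list(...)
  truth_args <- opts[names(opts) %in% names(formals(sample_ground_truth))]
  data_args <- opts[names(opts) %in% setdiff(names(formals(sample_dataset)),
                                             c("truth", "seed"))]
  truth <- do.call(sample_ground_truth,
                   c(list(seed = as.integer(seed)), truth_args))
  bench <- do.call(sample_dataset,
                   c(list(truth = truth, seed = as.integer(seed) + 1L), data_args))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_io(sprintf("cannot create directory %s", dir))
  write_dataset(bench$dataset, dir, "dataset")
  write_dataset(bench$test, dir, "test")
  write_dataset(bench$candidates, dir, "candidates")
  for (k in VIEW_ORDER)
    write_matrix_csv(truth$W[[k]], file.path(dir, paste0("truth_W_", k, ".csv")))
  write_matrix_csv(truth$prototypes, file.path(dir, "truth_prototypes.csv"))
  if (!is.null(bench$hidden$add_brain))
    write_matrix_csv(bench$hidden$add_brain, file.path(dir, "hidden_add_brain.csv"))
  manifest <- list(role = "benchmark", seed = as.integer(seed),
                   truth_options = c(truth_args,
                                     list(snr = truth$snr, tau = truth$tau,
                                          prototype_shift = truth$prototype_shift,
                                          source_spread = truth$source_spread)),
                   data_options = data_args,
                   beta_true = as.list(truth$beta),
                   categories = list(source = truth$source, target = truth$target,
                                     distractor = truth$distractor),
                   files = list(dataset = "dataset.json", test = "test.json",
                                candidates = "candidates.json"))
  path <- file.path(dir, "benchmark.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
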