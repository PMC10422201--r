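#' Multi-view dataset for semi-supervised decoding
#'
#' Bundles the paired training block (brain activity, visual features and
#' semantic features measured for the same stimuli) with an optional
#' additional block of visual/semantic features for which no brain activity
#' was recorded.  All matrices are features x samples.
#'
#' @param brain numeric matrix, voxels x N.
#' @param visual numeric matrix, visual feature dim x N.
#' @param semantic numeric matrix, semantic feature dim x N.
#' @param paired_labels character vector of category names, length N.
#' @param add_visual,add_semantic optional matrices with M columns for the
#'   additional (unpaired) samples; both present or both absent.
#' @param add_labels category names for the additional samples, length M.
#' @param zero_shot logical; when `TRUE` (the default) no category may occur
#'   in both the paired and the additional block.
#' @return an object of class `mv_dataset`.
#' @export
multiview_dataset <- function(brain, visual, semantic, paired_labels,
                              add_visual = NULL, add_semantic = NULL,
                              add_labels = character(0), zero_shot = TRUE) {
  brain <- as_matrix(brain, "brain"); visual <- as_matrix(visual, "visual")
  semantic <- as_matrix(semantic, "semantic")
  n <- ncol(brain)
  if (ncol(visual) != n || ncol(semantic) != n)
    stop_shape(sprintf(
      "paired blocks disagree on sample count: brain %d, visual %d, semantic %d",
      n, ncol(visual), ncol(semantic)))
  if (length(paired_labels) != n)
    stop_shape("paired_labels length must equal the paired sample count")
  if (is.null(add_visual) != is.null(add_semantic))
    stop_invalid("add_visual and add_semantic must be given together")
  if (is.null(add_visual)) {
    add_visual <- matrix(0, nrow(visual), 0)
    add_semantic <- matrix(0, nrow(semantic), 0)
  }
  add_visual <- as_matrix(add_visual, "add_visual")
  add_semantic <- as_matrix(add_semantic, "add_semantic")
  m <- ncol(add_visual)
  if (ncol(add_semantic) != m)
    stop_shape("add_visual and add_semantic disagree on sample count")
  if (nrow(add_visual) != nrow(visual) || nrow(add_semantic) != nrow(semantic))
    stop_shape("additional blocks disagree with paired blocks on feature dimension")
  if (length(add_labels) != m)
    stop_shape("add_labels length must equal the additional sample count")
  for (nm in c("brain", "visual", "semantic", "add_visual", "add_semantic"))
    check_finite(get(nm), nm)
  if (zero_shot && m > 0) {
    shared <- intersect(unique(paired_labels), unique(add_labels))
    if (length(shared) > 0)
      stop_invalid(sprintf(
        "zero-shot dataset shares categories between paired and additional blocks: %s",
        paste(shared, collapse = ", ")))
  }
  structure(list(brain = brain, visual = visual, semantic = semantic,
                 paired_labels = as.character(paired_labels),
                 add_visual = add_visual, add_semantic = add_semantic,
                 add_labels = as.character(add_labels),
                 zero_shot = isTRUE(zero_shot)),
            class = "mv_dataset")
}

#' @export
print.mv_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "Multi-view dataset: %d paired samples (%d categories), ",
    "%d additional samples (%d categories)%s\n"),
    ncol(x$brain), length(unique(x$paired_labels)),
    ncol(x$add_visual), length(unique(x$add_labels)),
    if (x$zero_shot) " [zero-shot split]" else ""))
  cat(sprintf("  dims: brain %d, visual %d, semantic %d\n",
              nrow(x$brain), nrow(x$visual), nrow(x$semantic)))
  invisible(x)
}

#' Candidate-category reference vectors for decoding
#'
#' @param names unique category names (length C >= 2).
#' @param visual matrix Dv x C of per-category visual reference vectors.
#' @param semantic matrix Ds x C of per-category semantic reference vectors.
#' @return an object of class `mv_candidates`.
#' @export
candidate_set <- function(names, visual, semantic) {
  visual <- as_matrix(visual, "visual"); semantic <- as_matrix(semantic, "semantic")
  names <- as.character(names)
  if (length(names) < 2) stop_invalid("a candidate set needs at least 2 categories")
  if (anyDuplicated(names)) stop_invalid("candidate names must be unique")
  if (ncol(visual) != length(names) || ncol(semantic) != length(names))
    stop_shape("candidate matrices must have one column per category name")
  check_finite(visual, "candidate visual"); check_finite(semantic, "candidate semantic")
  structure(list(names = names, visual = visual, semantic = semantic),
            class = "mv_candidates")
}

#' Test brain activity with ground-truth category labels
#'
#' @param brain matrix Df x n_test of test brain-activity vectors.
#' @param true_labels category name per test sample.
#' @param candidates optional companion [candidate_set()]; when given, every
#'   true label must appear among its names.
#' @return an object of class `mv_testset`.
#' @export
test_set <- function(brain, true_labels, candidates = NULL) {
  brain <- as_matrix(brain, "brain_test")
  check_finite(brain, "brain_test")
  true_labels <- as.character(true_labels)
  if (length(true_labels) != ncol(brain))
    stop_shape("true_labels length must equal the number of test samples")
  if (!is.null(candidates)) {
    missing <- setdiff(unique(true_labels), candidates$names)
    if (length(missing) > 0)
      stop_invalid(sprintf("test labels absent from candidate set: %s",
                           paste(missing, collapse = ", ")))
  }
  structure(list(brain = brain, true_labels = true_labels), class = "mv_testset")
}

# ---- standardization -------------------------------------------------------

#' Fit per-feature standardization statistics
#'
#' Computes, for each feature (row) of a view matrix, the mean and standard
#' deviation across samples.  Features with zero variance are flagged;
#' [standardize_apply()] maps them to 0 rather than dividing by zero, since
#' real voxel data routinely contains dead channels.
#'
#' @param x view matrix, features x samples.
#' @return an object of class `mv_standardization` with fields `mean`, `sd`
#'   and logical `zero_var`.
#' @export
standardize_fit <- function(x) {
  x <- as_matrix(x, "matrix")
  if (length(x) == 0) stop_invalid("cannot standardize an empty matrix")
  check_finite(x, "matrix")
  mu <- rowMeans(x)
  # population SD (divide by n): z-scored features get SD exactly 1
  sd <- sqrt(rowMeans((x - mu)^2))
  structure(list(mean = mu, sd = sd, zero_var = sd == 0),
            class = "mv_standardization")
}

#' Apply (or invert) standardization statistics
#'
#' @param x view matrix, features x samples.
#' @param stats an `mv_standardization` object fitted on training data.
#' @return matrix of the same shape; zero-variance features map to 0.
#' @export
standardize_apply <- function(x, stats) {
  x <- as_matrix(x, "matrix")
  if (nrow(x) != length(stats$mean))
    stop_invalid(sprintf("feature dimension %d does not match stats (%d)",
                         nrow(x), length(stats$mean)))
  denom <- ifelse(stats$zero_var, 1, stats$sd)
  out <- (x - stats$mean) / denom
  out[stats$zero_var, ] <- 0
  out
}

#' @rdname standardize_apply
#' @export
standardize_invert <- function(x, stats) {
  x <- as_matrix(x, "matrix")
  if (nrow(x) != length(stats$mean))
    stop_invalid("feature dimension does not match stats")
  denom <- ifelse(stats$zero_var, 1, stats$sd)
  x * denom + stats$mean
}

#' Standardize a dataset, test set and candidate set consistently
#'
#' Statistics are fitted on the paired training block only and applied to the
#' additional block, the test brain activity and the candidate vectors, so no
#' information flows from test data into the preprocessing.
#'
#' @param dataset an [multiview_dataset()] object.
#' @param test optional [test_set()].
#' @param candidates optional [candidate_set()].
#' @param extra_brain optional Df x M matrix (e.g. withheld true brain
#'   activity of the additional samples) standardized with the brain stats.
#' @return list with standardized `dataset`, `test`, `candidates`,
#'   `extra_brain`, and `stats` (per-view `mv_standardization`).
#' @export
standardize_bundle <- function(dataset, test = NULL, candidates = NULL,
                               extra_brain = NULL) {
  stats <- list(brain = standardize_fit(dataset$brain),
                visual = standardize_fit(dataset$visual),
                semantic = standardize_fit(dataset$semantic))
  ds <- dataset
  ds$brain <- standardize_apply(dataset$brain, stats$brain)
  ds$visual <- standardize_apply(dataset$visual, stats$visual)
  ds$semantic <- standardize_apply(dataset$semantic, stats$semantic)
  if (ncol(ds$add_visual) > 0) {
    ds$add_visual <- standardize_apply(dataset$add_visual, stats$visual)
    ds$add_semantic <- standardize_apply(dataset$add_semantic, stats$semantic)
  }
  if (!is.null(test)) test$brain <- standardize_apply(test$brain, stats$brain)
  if (!is.null(candidates)) {
    candidates$visual <- standardize_apply(candidates$visual, stats$visual)
    candidates$semantic <- standardize_apply(candidates$semantic, stats$semantic)
  }
  if (!is.null(extra_brain))
    extra_brain <- standardize_apply(extra_brain, stats$brain)
  list(dataset = ds, test = test, candidates = candidates,
       extra_brain = extra_brain, stats = stats)
}

# ---- manifest I/O ----------------------------------------------------------

#' Write a dataset object to a manifest bundle
#'
#' Matrices are written as comma-separated text with one sample per row and a
#' header of feature indices, alongside a JSON manifest recording roles,
#' orientations and labels.  [load_dataset()] reads the manifest back.
#'
#' @param obj an `mv_dataset`, `mv_testset` or `mv_candidates` object.
#' @param dir output directory (created if needed).
#' @param name basename for the manifest file.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(obj, dir, name = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_io(sprintf("cannot create directory %s", dir))
  rel <- function(p) file.path(dir, p)
  if (inherits(obj, "mv_dataset")) {
    name <- name %||% "dataset"
    mats <- list(brain = obj$brain, visual = obj$visual, semantic = obj$semantic,
                 add_visual = obj$add_visual, add_semantic = obj$add_semantic)
    files <- paste0(name, "_", names(mats), ".csv")
    for (i in seq_along(mats)) write_matrix_csv(mats[[i]], rel(files[i]))
    manifest <- list(role = "multiview_dataset", zero_shot = obj$zero_shot,
                     matrices = stats::setNames(lapply(files, function(f)
                       list(path = f, orientation = "samples_x_features")),
                       names(mats)),
                     labels = list(paired = obj$paired_labels,
                                   additional = obj$add_labels))
  } else if (inherits(obj, "mv_testset")) {
    name <- name %||% "test"
    f <- paste0(name, "_brain.csv")
    write_matrix_csv(obj$brain, rel(f))
    manifest <- list(role = "test_set",
                     matrices = list(brain = list(path = f,
                                                  orientation = "samples_x_features")),
                     labels = list(true = obj$true_labels))
  } else if (inherits(obj, "mv_candidates")) {
    name <- name %||% "candidates"
    fv <- paste0(name, "_visual.csv"); fs <- paste0(name, "_semantic.csv")
    write_matrix_csv(obj$visual, rel(fv)); write_matrix_csv(obj$semantic, rel(fs))
    manifest <- list(role = "candidate_set",
                     matrices = list(
                       visual = list(path = fv, orientation = "samples_x_features"),
                       semantic = list(path = fs, orientation = "samples_x_features")),
                     labels = list(names = obj$names))
  } else stop_invalid("write_dataset: unsupported object class")
  mpath <- rel(paste0(name, ".json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Load a dataset object from a JSON manifest
#'
#' @param manifest path to a manifest written by [write_dataset()] (or built
#'   by hand with the same keys: `role`, `matrices` with per-matrix `path`
#'   and `orientation`, `labels`).
#' @return an `mv_dataset`, `mv_testset` or `mv_candidates` object, validated.
#' @export
load_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop_load(sprintf("manifest not found: %s", manifest))
  spec <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  get_mat <- function(key) {
    entry <- spec$matrices[[key]]
    if (is.null(entry)) stop_load(sprintf("manifest lacks matrix '%s'", key))
    read_matrix_csv(file.path(dir, entry$path),
                    entry$orientation %||% "samples_x_features")
  }
  role <- spec$role %||% "unknown"
  if (role == "multiview_dataset") {
    multiview_dataset(get_mat("brain"), get_mat("visual"), get_mat("semantic"),
                      paired_labels = unlist(spec$labels$paired),
                      add_visual = get_mat("add_visual"),
                      add_semantic = get_mat("add_semantic"),
                      add_labels = as.character(unlist(spec$labels$additional) %||% character(0)),
                      zero_shot = isTRUE(spec$zero_shot))
  } else if (role == "test_set") {
    test_set(get_mat("brain"), unlist(spec$labels$true))
  } else if (role == "candidate_set") {
    nm <- unlist(spec$labels$names)
    if (anyDuplicated(nm)) stop_load("duplicate candidate names in manifest")
    candidate_set(nm, get_mat("visual"), get_mat("semantic"))
  } else stop_load(sprintf("unknown manifest role '%s'", role))
}

#' Write predictions or a metrics record to disk
#'
#' Prediction matrices go to delimited text; metrics records go to JSON with
#' the run configuration and seed embedded so every number is auditable.
#'
#' @param obj a numeric matrix of predictions, or a named list of metrics.
#' @param path output file path.
#' @param config optional configuration echoed into metrics JSON.
#' @param seed optional seed echoed into metrics JSON.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, config = NULL, seed = NULL) {
  if (is.matrix(obj) || is.numeric(obj)) {
    obj <- as_matrix(obj, "predictions")
    if (!all(is.finite(obj))) stop_invalid("refusing to write non-finite predictions")
    write_matrix_csv(obj, path)
  } else if (is.list(obj)) {
    vals <- unlist(obj, use.names = FALSE)
    if (is.numeric(vals) && !all(is.finite(vals)))
      stop_invalid("refusing to write non-finite metrics")
    out <- list(metrics = obj,
                config = config,
                seed = seed,
                package_version = as.character(utils::packageVersion("mvgdecode")))
    ok <- tryCatch({
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_io(sprintf("cannot write %s", path))
  } else stop_invalid("write_results: unsupported object")
  invisible(path)
}
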