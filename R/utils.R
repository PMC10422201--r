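# Internal helpers: classed conditions, matrix text I/O, small utilities.

mvg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mvg_error"), call = call))
}

stop_invalid <- function(msg) mvg_stop(msg, "mvg_invalid_input")
stop_shape   <- function(msg) mvg_stop(msg, "mvg_shape_error")
stop_load    <- function(msg) mvg_stop(msg, "mvg_load_error")
stop_config  <- function(msg) mvg_stop(msg, "mvg_config_error")
stop_numeric <- function(msg) mvg_stop(msg, "mvg_numeric_error")
stop_io      <- function(msg) mvg_stop(msg, "mvg_io_error")

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_invalid(sprintf("non-finite entries in %s", what))
  invisible(x)
}

as_matrix <- function(x, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = length(x))
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid(sprintf("%s must be a numeric matrix", what))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

# Canonical view order used everywhere (update sweeps, RNG draws, output files).
VIEW_ORDER <- c("brain", "visual", "semantic")

order_views <- function(views) VIEW_ORDER[VIEW_ORDER %in% views]

# Matrices are stored on disk one sample per row, header giving feature
# indices; in memory everything is features x samples.  %.17g guarantees
# doubles survive the text roundtrip exactly.
write_matrix_csv <- function(x, path) {
  x <- as_matrix(x, "matrix")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(paste0("f", seq_len(nrow(x))), collapse = ","), con)
  if (ncol(x) > 0) {
    body <- apply(x, 2, function(col) paste(sprintf("%.17g", col), collapse = ","))
    writeLines(body, con)
  }
  invisible(path)
}

read_matrix_csv <- function(path, orientation = "samples_x_features") {
  if (!file.exists(path)) stop_load(sprintf("matrix file not found: %s", path))
  df <- utils::read.csv(path, header = TRUE, colClasses = "numeric",
                        check.names = FALSE)
  m <- t(as.matrix(df))           # -> features x samples
  dimnames(m) <- NULL
  if (identical(orientation, "features_x_samples")) m <- t(m)
  else if (!identical(orientation, "samples_x_features"))
    stop_load(sprintf("unknown orientation '%s'", orientation))
  if (anyNA(m) || !all(is.finite(m)))
    stop_load(sprintf("non-finite entries in matrix file %s", path))
  m
}

# FNV-1a over a string; used to name run directories by configuration.
config_hash <- function(x) {
  if (!is.character(x)) x <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE))
  bytes <- utf8ToInt(paste(x, collapse = "\n")) %% 256
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
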