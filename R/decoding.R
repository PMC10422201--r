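# Correlation-based zero-shot decoding against a candidate set, and the
# identification / rank metrics used to score it.

#' Pearson correlation with a defined value for constant vectors
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @return the Pearson correlation coefficient in `[-1, 1]`; if either
#'   vector is constant the correlation is undefined and 0 is returned with
#'   a warning, so one degenerate prediction cannot abort a whole evaluation.
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop_invalid("vectors must have equal length")
  if (length(a) < 2) stop_invalid("correlation needs at least 2 elements")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant vector: Pearson correlation undefined, returning 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Blend visual- and semantic-space correlations
#'
#' `r_combined = eta * r_visual + (1 - eta) * r_semantic`, the trade-off
#' between the two embedding spaces.
#'
#' @param r_visual,r_semantic correlation scores (may be vectors).
#' @param eta trade-off weight in `[0, 1]`; 1 uses the visual space only.
#' @return the convex combination.
#' @export
combined_score <- function(r_visual, r_semantic, eta) {
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) || eta < 0 || eta > 1)
    stop_invalid("eta must be a single value in [0, 1]")
  eta * r_visual + (1 - eta) * r_semantic
}

# Correlations between one predicted vector and every candidate column.
candidate_correlations <- function(pred, cand) {
  pred <- as.numeric(pred)
  if (length(pred) != nrow(cand))
    stop_invalid("prediction length does not match candidate dimension")
  vapply(seq_len(ncol(cand)), function(j) {
    suppressWarnings(pearson_r(pred, cand[, j]))
  }, 0)
}

#' Score every candidate for one test sample
#'
#' @param pred_visual,pred_semantic predicted feature vectors for one test
#'   sample; either may be `NULL` when the model lacks that view (its
#'   correlation then contributes 0 to the blend).
#' @param candidates an [candidate_set()].
#' @param eta trade-off weight in `[0, 1]`.
#' @return object of class `mvg_scores`: per-candidate `r_visual`,
#'   `r_semantic`, `combined`, plus `eta` and the candidate `names`.
#' @export
decoding_scores <- function(pred_visual, pred_semantic, candidates, eta) {
  n_cand <- length(candidates$names)
  if (n_cand < 2) stop_invalid("need at least 2 candidate categories")
  r_v <- if (is.null(pred_visual)) rep(0, n_cand)
         else candidate_correlations(pred_visual, candidates$visual)
  r_s <- if (is.null(pred_semantic)) rep(0, n_cand)
         else candidate_correlations(pred_semantic, candidates$semantic)
  structure(list(r_visual = r_v, r_semantic = r_s,
                 combined = combined_score(r_v, r_s, eta),
                 eta = eta, names = candidates$names),
            class = "mvg_scores")
}

#' Decode the viewed category for one test sample
#'
#' Scores every candidate by blended correlation and picks the argmax; score
#' ties are broken towards the lowest candidate index.
#'
#' @inheritParams decoding_scores
#' @param true_label optional ground-truth category name; when given, the
#'   result carries the truth's rank and pairwise identification accuracy.
#' @return object of class `mvg_decoding`: `decoded` (category name),
#'   `scores` (`mvg_scores`), and when the truth is known `rank` and
#'   `pairwise_accuracy`.
#' @export
decode_category <- function(pred_visual, pred_semantic, candidates, eta,
                            true_label = NULL) {
  sc <- decoding_scores(pred_visual, pred_semantic, candidates, eta)
  out <- list(decoded = sc$names[which.max(sc$combined)], scores = sc)
  if (!is.null(true_label)) {
    ti <- match(true_label, sc$names)
    if (is.na(ti)) stop_invalid(sprintf("true label '%s' not a candidate", true_label))
    out$rank <- rank_of_truth(sc$combined, ti)
    out$pairwise_accuracy <- pairwise_identification_accuracy(sc$combined, ti)
  }
  structure(out, class = "mvg_decoding")
}

#' Pairwise (two-alternative) identification accuracy
#'
#' For each of the C-1 opponent candidates the truth wins if its combined
#' score is strictly higher; exact ties are credited one half, the standard
#' two-alternative forced-choice convention.  Chance level is 50%.
#'
#' @param scores numeric vector of combined scores over all C candidates, or
#'   an `mvg_scores` object.
#' @param true_index position of the ground-truth candidate.
#' @return fraction of opponent pairs won, in `[0, 1]`.
#' @export
pairwise_identification_accuracy <- function(scores, true_index) {
  if (inherits(scores, "mvg_scores")) scores <- scores$combined
  n_cand <- length(scores)
  if (n_cand < 2) stop_invalid("need at least 2 candidates")
  if (!is.numeric(true_index) || length(true_index) != 1 ||
      is.na(true_index) || true_index < 1 || true_index > n_cand)
    stop_invalid("true_index out of range")
  s <- scores[true_index]
  opp <- scores[-true_index]
  (sum(opp < s) + 0.5 * sum(opp == s)) / (n_cand - 1)
}

#' Rank of the ground-truth candidate
#'
#' Rank 1 means the truth scores highest; opponents tying with the truth are
#' counted as ahead of it (the conservative reading).
#'
#' @inheritParams pairwise_identification_accuracy
#' @return integer rank in `[1, C]`.
#' @export
rank_of_truth <- function(scores, true_index) {
  if (inherits(scores, "mvg_scores")) scores <- scores$combined
  n_cand <- length(scores)
  if (true_index < 1 || true_index > n_cand) stop_invalid("true_index out of range")
  1L + sum(scores[-true_index] >= scores[true_index])
}

#' Rank-n accuracy over a set of test samples
#'
#' The fraction of test samples whose ground-truth category ranks within the
#' top n of all C candidates; chance level is n/C for continuous scores.
#'
#' @param ranks integer vector of ground-truth ranks, one per test sample
#'   (from [rank_of_truth()] or [decode_category()]).
#' @param n rank cutoff, `1 <= n <= n_candidates`.
#' @param n_candidates the candidate-set size C.
#' @return fraction in `[0, 1]`.
#' @export
rank_n_accuracy <- function(ranks, n, n_candidates) {
  if (n < 1 || n > n_candidates) stop_invalid("n must lie in [1, n_candidates]")
  if (any(ranks < 1 | ranks > n_candidates)) stop_invalid("rank outside [1, C]")
  mean(ranks <= n)
}

#' Distance between a group embedding and its prototype
#'
#' The group embedding is the mean predicted feature vector over a group's
#' categories, the prototype the mean ground-truth vector over the same
#' categories; their Euclidean distance measures how far the projection
#' drifts from where the group truly lives (the projection-domain-shift
#' diagnostic).
#'
#' @param embeddings matrix Di x G of predicted per-category vectors (or a
#'   single vector).
#' @param prototypes matrix Di x G of ground-truth per-category vectors.
#' @return the L2 norm of (mean embedding - mean prototype).
#' @export
prototype_distance <- function(embeddings, prototypes) {
  embeddings <- as_matrix(embeddings, "embeddings")
  prototypes <- as_matrix(prototypes, "prototypes")
  if (ncol(embeddings) == 0 || ncol(prototypes) == 0)
    stop_invalid("empty group")
  if (nrow(embeddings) != nrow(prototypes))
    stop_invalid("embedding and prototype dimensions differ")
  sqrt(sum((rowMeans(embeddings) - rowMeans(prototypes))^2))
}

#' Evaluate decoding over a test set, optionally on an eta grid
#'
#' For every eta value, every test sample is scored against the candidate
#' set and the identification metrics are aggregated.  Reporting the whole
#' grid makes the dependence on the trade-off parameter visible instead of
#' silently selecting the best value.
#'
#' @param pred_visual,pred_semantic Di x n_test matrices of predicted means
#'   (either may be `NULL`).
#' @param test an [test_set()].
#' @param candidates an [candidate_set()].
#' @param etas numeric vector of trade-off weights (default the grid
#'   `0, 0.1, ..., 1`).
#' @param rank_cutoffs integer vector of rank-n cutoffs to report.
#' @return data frame with one row per eta: mean pairwise accuracy, mean
#'   rank, and one rank-n accuracy column per cutoff.
#' @export
evaluate_decoding <- function(pred_visual, pred_semantic, test, candidates,
                              etas = seq(0, 1, by = 0.1),
                              rank_cutoffs = integer(0)) {
  n_test <- ncol(test$brain)
  n_cand <- length(candidates$names)
  true_idx <- match(test$true_labels, candidates$names)
  if (anyNA(true_idx)) stop_invalid("test labels absent from candidate set")
  rv <- rs <- matrix(0, n_test, n_cand)
  for (i in seq_len(n_test)) {
    if (!is.null(pred_visual))
      rv[i, ] <- candidate_correlations(pred_visual[, i], candidates$visual)
    if (!is.null(pred_semantic))
      rs[i, ] <- candidate_correlations(pred_semantic[, i], candidates$semantic)
  }
  rows <- lapply(etas, function(eta) {
    comb <- eta * rv + (1 - eta) * rs
    pw <- vapply(seq_len(n_test), function(i)
      pairwise_identification_accuracy(comb[i, ], true_idx[i]), 0)
    rk <- vapply(seq_len(n_test), function(i)
      rank_of_truth(comb[i, ], true_idx[i]), 0L)
    row <- data.frame(eta = eta, pairwise_accuracy = mean(pw),
                      mean_rank = mean(rk))
    for (n in rank_cutoffs)
      row[[paste0("rank", n, "_accuracy")]] <- rank_n_accuracy(rk, n, n_cand)
    row
  })
  do.call(rbind, rows)
}
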