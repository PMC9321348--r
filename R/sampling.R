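#' Positive miRNA-disease pairs of an association matrix
#'
#' @param A Binary association matrix.
#' @return Tibble with `mirna`, `disease` (integer indices) and `label = 1`.
#' @export
positive_pairs <- function(A) {
  idx <- which(A != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(mirna = unname(idx[, 1L]), disease = unname(idx[, 2L]),
                 label = 1L)
}

#' Sample unobserved pairs as negatives
#'
#' Draws a uniform sample, without replacement, from the zero entries of the
#' association matrix. The negative count is `round(ratio * n_positives)`
#' (ratios 1:1 up to 1:5 correspond to `ratio` 1..5).
#'
#' @param A Binary association matrix.
#' @param ratio Negatives per positive.
#' @param seed Optional integer seed (set for a reproducible draw).
#' @return Tibble with `mirna`, `disease`, `label = 0`.
#' @export
sample_negatives <- function(A, ratio = 1, seed = NULL) {
  stopifnot(ratio > 0)
  zeros <- which(A == 0)
  n_pos <- sum(A != 0)
  n_neg <- round(ratio * n_pos)
  if (length(zeros) < n_neg) {
    abort(paste0("Cannot draw ", n_neg, " negatives: only ", length(zeros),
                 " unobserved pairs available."))
  }
  if (!is.null(seed)) set.seed(seed)
  pick <- sort(sample(zeros, n_neg))
  tibble::tibble(mirna = as.integer((pick - 1L) %% nrow(A) + 1L),
                 disease = as.integer((pick - 1L) %/% nrow(A) + 1L),
                 label = 0L)
}

#' Labeled pair set: positives plus sampled negatives
#'
#' @inheritParams sample_negatives
#' @return Tibble with `mirna`, `disease`, `label` (positives first).
#' @export
pair_dataset <- function(A, ratio = 1, seed = NULL) {
  dplyr::bind_rows(positive_pairs(A), sample_negatives(A, ratio, seed))
}

#' Positive-cluster vector and average Euclidean distance of negatives
#'
#' The cluster vector is the coordinatewise mean of the positive pair
#' features; the AED is the mean Euclidean distance between each negative
#' feature vector and that cluster vector.
#'
#' @param pos_features,neg_features Feature matrices (one pair per row) for
#'   positive and candidate-negative pairs.
#' @return List with `cluster` (numeric vector), `aed` (scalar) and
#'   `distances` (per-negative distances to the cluster).
#' @export
compute_cluster_aed <- function(pos_features, neg_features) {
  pos_features <- as.matrix(pos_features)
  neg_features <- as.matrix(neg_features)
  if (nrow(pos_features) == 0L || nrow(neg_features) == 0L) {
    abort("Need at least one positive and one negative feature vector.")
  }
  stopifnot(ncol(pos_features) == ncol(neg_features))
  cluster <- colMeans(pos_features)
  dif <- sweep(neg_features, 2L, cluster)
  distances <- sqrt(rowSums(dif^2))
  list(cluster = cluster, aed = mean(distances), distances = distances)
}

#' Reliable-negative filter by distance to the positive cluster
#'
#' Removes candidate negatives whose distance to the positive-cluster vector
#' is strictly lower than `threshold_frac * AED`; distances exactly at the
#' threshold are retained. Negatives far from the positive centroid are the
#' more reliable non-associations.
#'
#' @param negatives Tibble of candidate negative pairs (one row per
#'   negative, aligned with `distances`).
#' @param distances Per-negative distances to the cluster vector (from
#'   [compute_cluster_aed()]).
#' @param aed The average Euclidean distance.
#' @param threshold_frac Threshold as a fraction of the AED, in `(0, 1]`
#'   (the studied grid is 0.4 to 1.0).
#' @return The retained subset of `negatives` (possibly empty, with a
#'   warning).
#' @export
aed_filter <- function(negatives, distances, aed, threshold_frac) {
  stopifnot(threshold_frac > 0, threshold_frac <= 1,
            nrow(negatives) == length(distances))
  keep <- distances >= threshold_frac * aed
  if (!any(keep)) {
    warn("AED filter removed every candidate negative.")
  }
  negatives[keep, , drop = FALSE]
}
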