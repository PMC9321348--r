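#' Pair feature vectors by embedding concatenation
#'
#' The feature vector of a pair `(i, j)` is the miRNA embedding row `i`
#' concatenated with the disease embedding row `j` (length `2d`), the input
#' representation for the classifier.
#'
#' @param embeddings An `mda_embeddings` object (or list with `Z_m`, `Z_d`).
#' @param pairs Tibble with integer columns `mirna` and `disease` (and
#'   optionally `label`).
#' @return List of class `pair_features`: `x` (feature matrix, rows in the
#'   order of `pairs`), `label` (or `NULL`), `pairs`.
#' @export
pair_features <- function(embeddings, pairs) {
  Z_m <- embeddings$Z_m
  Z_d <- embeddings$Z_d
  stopifnot(is.data.frame(pairs), all(c("mirna", "disease") %in% names(pairs)))
  if (nrow(pairs) > 0 &&
      (max(pairs$mirna) > nrow(Z_m) || min(pairs$mirna) < 1L ||
       max(pairs$disease) > nrow(Z_d) || min(pairs$disease) < 1L)) {
    abort("Pair indices out of range of the embedding matrices.")
  }
  x <- cbind(Z_m[pairs$mirna, , drop = FALSE], Z_d[pairs$disease, , drop = FALSE])
  rownames(x) <- NULL
  colnames(x) <- c(paste0("m", seq_len(ncol(Z_m))), paste0("d", seq_len(ncol(Z_d))))
  structure(list(x = x, label = pairs[["label"]], pairs = pairs),
            class = "pair_features")
}

#' Train the RBF-kernel support vector classifier
#'
#' Fits a support vector machine with a radial-basis kernel on standardized
#' pair features. Standardization statistics (per-dimension mean and sd) are
#' computed on the training data only and stored with the model, so scoring
#' held-out pairs never uses test statistics. Probabilistic scores come from
#' sigmoid calibration of the decision values.
#'
#' @param features A `pair_features` object with labels, or a feature matrix.
#' @param label Binary labels (required when `features` is a matrix).
#' @param C Penalty factor (default 150; 50 is the alternative setting).
#' @param gamma RBF width; default `1 / (n_features * mean feature variance)`
#'   computed on the standardized training features.
#' @param seed Integer seed for the internal calibration fit.
#' @return An `mda_svm` model object.
#' @export
train_svm <- function(features, label = NULL, C = 150, gamma = NULL, seed = 1L) {
  if (inherits(features, "pair_features")) {
    label <- label %||% features$label
    x <- features$x
  } else {
    x <- as.matrix(features)
  }
  if (is.null(label)) abort("Training labels are required.")
  y <- factor(as.integer(label != 0), levels = c(0L, 1L))
  if (length(unique(y)) < 2L) {
    abort("Both classes must be present to train the classifier.")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2L, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  if (is.null(gamma)) {
    v <- mean(apply(xs, 2L, var))
    if (!is.finite(v) || v <= 0) v <- 1
    gamma <- 1 / (ncol(xs) * v)
  }
  set.seed(seed)
  fit <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, probability = TRUE, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale_, C = C,
                 gamma = gamma, n_train = nrow(xs),
                 class_counts = table(y)),
            class = "mda_svm")
}

#' @export
print.mda_svm <- function(x, ...) {
  cat("<mda_svm> RBF support vector classifier: C = ", x$C,
      ", gamma = ", signif(x$gamma, 4), ", ", x$fit$tot.nSV,
      " support vectors, ", x$n_train, " training pairs\n", sep = "")
  invisible(x)
}

#' @export
tidy.mda_svm <- function(x, ...) {
  tibble::tibble(
    term = c("C", "gamma", "n_support_vectors", "n_train"),
    estimate = c(x$C, x$gamma, x$fit$tot.nSV, x$n_train)
  )
}

#' @export
glance.mda_svm <- function(x, ...) {
  tibble::tibble(C = x$C, gamma = x$gamma, n_support_vectors = x$fit$tot.nSV,
                 n_train = x$n_train)
}

#' Score miRNA-disease pairs with a trained classifier
#'
#' Returns the calibrated association probability and the raw decision value
#' for each pair. Higher scores indicate stronger predicted association;
#' the probability ranking is used for the case-study tables and the raw
#' decision value is available for threshold-free curves.
#'
#' @param model An `mda_svm` from [train_svm()].
#' @param features A `pair_features` object or feature matrix (same feature
#'   space as the training data).
#' @return Tibble with `mirna`/`disease` (when available), `score`
#'   (probability in `[0, 1]`) and `decision` (signed decision value).
#' @export
score_pairs <- function(model, features) {
  stopifnot(inherits(model, "mda_svm"))
  pairs <- NULL
  if (inherits(features, "pair_features")) {
    pairs <- features$pairs
    x <- features$x
  } else {
    x <- as.matrix(features)
  }
  if (ncol(x) != length(model$center)) {
    abort("Feature dimension does not match the trained model.")
  }
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  pr <- predict(model$fit, xs, probability = TRUE, decision.values = TRUE)
  prob <- attr(pr, "probabilities")[, "1"]
  dec <- drop(attr(pr, "decision.values"))
  # e1071 orients the decision value by the first training label; align it
  # so larger decision always means more positive
  flip <- suppressWarnings(stats::cor(prob, dec))
  if (is.finite(flip) && flip < 0) dec <- -dec
  out <- tibble::tibble(score = unname(prob), decision = unname(dec))
  if (!is.null(pairs)) out <- dplyr::bind_cols(pairs, out)
  out
}
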