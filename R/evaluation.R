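#' Heterogeneous network container
#'
#' Bundles the inputs of the prediction pipeline: the miRNA-disease
#' association matrix, the miRNA-protein and disease-protein association
#' matrices, and the disease hierarchy.
#'
#' @param A Binary miRNA-by-disease association matrix (with `dimnames`).
#' @param MP Binary miRNA-by-protein matrix, rows aligned with `rownames(A)`.
#' @param DP Binary disease-by-protein matrix, rows aligned with
#'   `colnames(A)`.
#' @param dag A `disease_dag` over (a subset of) the diseases.
#' @param sigma Semantic decay factor used for disease similarity.
#' @return An `mda_network` object.
#' @export
mda_network <- function(A, MP, DP, dag, sigma = 0.5) {
  stopifnot(nrow(MP) == nrow(A), nrow(DP) == ncol(A),
            inherits(dag, "disease_dag"))
  structure(list(A = A, MP = MP, DP = DP, dag = dag, sigma = sigma),
            class = "mda_network")
}

#' @export
print.mda_network <- function(x, ...) {
  cat("<mda_network> ", nrow(x$A), " miRNAs x ", ncol(x$A), " diseases (",
      sum(x$A), " associations, density ",
      signif(100 * mean(x$A != 0), 3), "%), ", ncol(x$MP), " proteins\n",
      sep = "")
  invisible(x)
}

# coerce synthetic datasets / plain lists to the network container
as_mda_network <- function(x) {
  if (inherits(x, "mda_network")) return(x)
  if (inherits(x, "mda_synthetic")) {
    return(mda_network(x$A_obs, x$MP, x$DP, x$dag))
  }
  if (is.list(x) && all(c("A", "MP", "DP", "dag") %in% names(x))) {
    return(mda_network(x$A, x$MP, x$DP, x$dag, x$sigma %||% 0.5))
  }
  abort("Cannot interpret input as an mda_network.")
}

#' Learn node embeddings for a heterogeneous network
#'
#' Runs the feature side of the pipeline: integrated similarities,
#' meta-path modules, and encoder pretraining.
#'
#' @param net An `mda_network` (or coercible object).
#' @param config An [encoder_config()].
#' @param A_train Optional replacement association matrix (e.g. with
#'   held-out fold positives masked out); defaults to `net$A`. Similarities,
#'   meta-paths and the reconstruction target are all computed from it, so
#'   held-out associations never leak into the embeddings.
#' @return An `mda_embeddings` object.
#' @export
learn_embeddings <- function(net, config = encoder_config(), A_train = NULL) {
  net <- as_mda_network(net)
  A <- A_train %||% net$A
  sims <- integrated_similarities(A, net$dag, sigma = net$sigma)
  modules <- build_modules(A, sims$MS, sims$DS, net$MP, net$DP)
  pretrain_embeddings(modules, A, config)
}

# ---- metrics -------------------------------------------------------------

#' ROC curve points
#'
#' Exact ROC step function: one point per distinct score threshold, ties
#' grouped. The implied AUC (trapezoidal rule over these points) equals the
#' tie-corrected Mann-Whitney statistic.
#'
#' @param labels Binary labels (0/1).
#' @param scores Numeric scores, larger = more positive.
#' @return Tibble with `threshold`, `fpr`, `tpr`, starting at (0, 0).
#' @export
roc_points <- function(labels, scores) {
  labels <- as.integer(labels != 0)
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(l)
  fp <- cumsum(1L - l)
  last <- which(!duplicated(s, fromLast = TRUE)) # tie-group right endpoints
  P <- sum(l)
  N <- length(l) - P
  tibble::tibble(threshold = c(Inf, s[last]),
                 fpr = c(0, fp[last] / N),
                 tpr = c(0, tp[last] / P))
}

#' Precision-recall curve points
#'
#' @inheritParams roc_points
#' @return Tibble with `threshold`, `recall`, `precision` (ties grouped).
#' @export
pr_points <- function(labels, scores) {
  labels <- as.integer(labels != 0)
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(l)
  fp <- cumsum(1L - l)
  last <- which(!duplicated(s, fromLast = TRUE))
  P <- sum(l)
  tibble::tibble(threshold = s[last],
                 recall = tp[last] / P,
                 precision = tp[last] / (tp[last] + fp[last]))
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L) {
    abort("Threshold-free metrics need both classes present.")
  }
}

#' Area under the ROC curve
#'
#' Trapezoidal rule over the exact ROC step function of [roc_points()].
#'
#' @inheritParams roc_points
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  pts <- roc_points(labels, scores)
  sum(diff(pts$fpr) * (head(pts$tpr, -1L) + pts$tpr[-1L]) / 2)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: precision weighted by recall increments.
#'
#' @inheritParams roc_points
#' @return Scalar AUPR in `(0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  pts <- pr_points(labels, scores)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' Threshold and ranking metrics for scored pairs
#'
#' Confusion counts at the given score threshold plus the derived metrics
#' (accuracy, precision, specificity = TN / (TN + FP), sensitivity, F1,
#' Matthews correlation), and the threshold-free AUC and AUPR from the score
#' ranking.
#'
#' @param labels Binary labels.
#' @param scores Scores in `[0, 1]` (calibrated probabilities).
#' @param threshold Classification threshold on the scores (default 0.5).
#' @return One-row tibble with `TP`, `TN`, `FP`, `FN`, `Acc`, `Pre`, `Spec`,
#'   `Sens`, `F1`, `Mcc`, `AUC`, `AUPR`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels != 0)
  stopifnot(length(labels) == length(scores))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  dplyr::bind_cols(
    tibble::tibble(TP = tp, TN = tn, FP = fp, FN = fn),
    confusion_metrics(tp, tn, fp, fn),
    tibble::tibble(AUC = roc_auc(labels, scores),
                   AUPR = pr_auc(labels, scores))
  )
}

# standard confusion-matrix metrics; undefined ratios fall back to 0
confusion_metrics <- function(tp, tn, fp, fn) {
  ratio0 <- function(num, den) if (den > 0) num / den else 0
  pre <- ratio0(tp, tp + fp)
  sens <- ratio0(tp, tp + fn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  tibble::tibble(
    Acc = (tp + tn) / (tp + tn + fp + fn),
    Pre = pre,
    Spec = ratio0(tn, tn + fp),
    Sens = sens,
    F1 = if (pre + sens > 0) 2 * pre * sens / (pre + sens) else 0,
    Mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  )
}

# ---- cross-validation ----------------------------------------------------

# stratified fold assignment: each class split as evenly as possible
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      abort(paste0("Class ", cls, " has fewer members (", length(idx),
                   ") than folds (", k, ")."))
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# derive a distinct sub-seed, kept inside 32-bit integer range
sub_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 7919 + a * 131 + b) %% 2147483647)
}

# one train/score pass for a fixed pair split; returns scored test pairs
fit_score_split <- function(net, train, test, encoder, C, aed_frac,
                            ratio, seed, mask = TRUE) {
  A_train <- net$A
  if (mask) {
    drop_pos <- test[test$label == 1L, , drop = FALSE]
    A_train[cbind(drop_pos$mirna, drop_pos$disease)] <- 0L
  }
  cfg <- encoder
  cfg$seed <- sub_seed(seed, 7L)
  emb <- learn_embeddings(net, cfg, A_train = A_train)
  if (!is.null(aed_frac)) {
    pos <- train[train$label == 1L, , drop = FALSE]
    neg <- train[train$label == 0L, , drop = FALSE]
    ca <- compute_cluster_aed(pair_features(emb, pos)$x,
                              pair_features(emb, neg)$x)
    kept <- aed_filter(neg, ca$distances, ca$aed, aed_frac)
    n_want <- min(round(ratio * nrow(pos)), nrow(kept))
    if (n_want < 1L) abort("AED filter left no usable training negatives.")
    set.seed(sub_seed(seed, 11L))
    kept <- kept[sample(nrow(kept), n_want), , drop = FALSE]
    train <- dplyr::bind_rows(pos, kept)
  }
  model <- train_svm(pair_features(emb, train), C = C,
                     seed = sub_seed(seed, 13L))
  score_pairs(model, pair_features(emb, test))
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' Builds a balanced (or `ratio`-imbalanced) labeled pair set from the
#' association matrix, assigns stratified folds, and for every fold retrains
#' the entire feature pipeline with the fold's positive associations masked
#' out of the association matrix (similarities, meta-paths and the encoder's
#' reconstruction target all see only training associations), trains the
#' classifier on the training pairs, and scores the held-out pairs. The
#' procedure is repeated `repeats` times with fresh negative samples and
#' fold assignments.
#'
#' @param net An `mda_network` or synthetic dataset.
#' @param k Number of folds.
#' @param repeats Number of repetitions of the whole procedure.
#' @param ratio Negatives per positive in the pair set.
#' @param aed_frac Optional reliable-negative threshold fraction in
#'   `(0, 1]`; `NULL` disables the filter.
#' @param encoder An [encoder_config()]; its seed is re-derived per fold.
#' @param C SVM penalty factor.
#' @param threshold Classification threshold for the thresholded metrics.
#' @param seed Master seed; every random step derives from it.
#' @param mask Mask test-fold positives out of the association matrix before
#'   computing similarities and embeddings (default `TRUE`; set `FALSE` for
#'   a literal no-masking replication).
#' @return An `mda_cv` object: `folds` (per-fold metric tibble), `summary`
#'   (grand mean and sd per metric), `scores` (per-fold labels and scores),
#'   and the settings.
#' @export
cross_validate <- function(net, k = 5L, repeats = 1L, ratio = 1,
                           aed_frac = NULL, encoder = encoder_config(),
                           C = 150, threshold = 0.5, seed = 1L, mask = TRUE) {
  net <- as_mda_network(net)
  folds_out <- list()
  scores_out <- list()
  for (r in seq_len(repeats)) {
    seed_r <- sub_seed(seed, 0L, r)
    pairs <- pair_dataset(net$A, ratio = ratio, seed = seed_r)
    set.seed(sub_seed(seed_r, 1L))
    fold <- stratified_folds(pairs$label, k)
    for (f in seq_len(k)) {
      test <- pairs[fold == f, , drop = FALSE]
      train <- pairs[fold != f, , drop = FALSE]
      scored <- fit_score_split(net, train, test, encoder, C, aed_frac,
                                ratio, seed = sub_seed(seed_r, 2L, f),
                                mask = mask)
      m <- compute_metrics(scored$label, scored$score, threshold)
      folds_out[[length(folds_out) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(repeat_ = r, fold = f), m)
      scores_out[[length(scores_out) + 1L]] <-
        tibble::tibble(repeat_ = r, fold = f,
                       label = scored$label, score = scored$score)
    }
  }
  folds <- dplyr::bind_rows(folds_out)
  metric_cols <- setdiff(names(folds), c("repeat_", "fold"))
  summary <- tidyr::pivot_longer(folds, dplyr::all_of(metric_cols),
                                 names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value), sd = sd(.data$value),
                              .groups = "drop")
  summary <- summary[match(metric_cols, summary$metric), ]
  structure(
    list(folds = folds, summary = summary,
         scores = dplyr::bind_rows(scores_out),
         settings = list(k = k, repeats = repeats, ratio = ratio,
                         aed_frac = aed_frac, C = C, threshold = threshold,
                         seed = seed, mask = mask, encoder = unclass(encoder))),
    class = "mda_cv"
  )
}

#' @export
print.mda_cv <- function(x, ...) {
  s <- x$settings
  cat("<mda_cv> ", s$k, "-fold x ", s$repeats, " repeat(s), ratio 1:",
      s$ratio, if (!is.null(s$aed_frac)) paste0(", AED frac ", s$aed_frac),
      "\n", sep = "")
  key <- x$summary[x$summary$metric %in% c("Acc", "AUC", "AUPR", "F1"), ]
  for (i in seq_len(nrow(key))) {
    cat(sprintf("  %-4s %.4f (sd %.4f)\n", key$metric[i], key$mean[i],
                key$sd[i]))
  }
  invisible(x)
}

#' @export
tidy.mda_cv <- function(x, ...) {
  x$folds
}

#' @export
glance.mda_cv <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(tibble::as_tibble(wide[c("Acc", "Pre", "Spec", "Sens",
                                            "F1", "Mcc", "AUC", "AUPR")]),
                   tibble::tibble(k = x$settings$k,
                                  repeats = x$settings$repeats,
                                  ratio = x$settings$ratio))
}

#' Plot cross-validation ROC curves
#'
#' One ROC step curve per fold plus the chance diagonal.
#'
#' @param object An `mda_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mda_cv <- function(object, ...) {
  curves <- dplyr::group_modify(
    dplyr::group_by(object$scores, .data$repeat_, .data$fold),
    function(d, g) roc_points(d$label, d$score)
  )
  curves <- dplyr::ungroup(curves)
  curves$id <- interaction(curves$repeat_, curves$fold)
  auc <- object$summary$mean[object$summary$metric == "AUC"]
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       group = .data$id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Cross-validated ROC (mean AUC %.3f)", auc)) +
    ggplot2::theme_minimal()
}

#' Write a cross-validation report to disk
#'
#' Writes the per-fold metrics as CSV and the grand means as a JSON summary.
#'
#' @param cv An `mda_cv` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "cv_folds.csv")
  utils::write.csv(cv$folds, csv, row.names = FALSE)
  js <- file.path(dir, "cv_summary.json")
  summary_list <- list(
    settings = cv$settings,
    mean = stats::setNames(as.list(cv$summary$mean), cv$summary$metric),
    sd = stats::setNames(as.list(cv$summary$sd), cv$summary$metric)
  )
  jsonlite::write_json(summary_list, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = js))
}

# ---- sweeps --------------------------------------------------------------

#' Sweep one pipeline parameter under shared seeds
#'
#' Re-runs [cross_validate()] over a grid of one parameter: the negative
#' ratio, the reliable-negative threshold fraction, or the embedding
#' dimension (grid values multiply `head_dim` while keeping `n_heads`).
#'
#' @param net An `mda_network` or synthetic dataset.
#' @param parameter One of `"ratio"`, `"aed_frac"`, `"dimension"`.
#' @param grid Numeric grid of parameter values.
#' @param ... Passed to [cross_validate()] (shared across grid points).
#' @return Tibble: one row per grid point with the grand-mean metrics.
#' @export
sweep_parameter <- function(net, parameter = c("ratio", "aed_frac", "dimension"),
                            grid, ...) {
  parameter <- match.arg(parameter)
  args <- list(...)
  rows <- lapply(grid, function(g) {
    a <- args
    if (parameter == "ratio") {
      a$ratio <- g
    } else if (parameter == "aed_frac") {
      a$aed_frac <- g
    } else {
      cfg <- a$encoder %||% encoder_config()
      stopifnot(g %% cfg$n_heads == 0)
      cfg$head_dim <- as.integer(g / cfg$n_heads)
      cfg$dim <- as.integer(g)
      a$encoder <- cfg
    }
    cv <- do.call(cross_validate, c(list(net), a))
    grid_col <- stats::setNames(tibble::tibble(g), parameter)
    gl <- glance(cv)
    gl[[parameter]] <- NULL
    dplyr::bind_cols(grid_col, gl)
  })
  dplyr::bind_rows(rows)
}

# ---- case-study ranking --------------------------------------------------

#' Rank candidate miRNAs for one disease
#'
#' Case-study protocol: the disease's known associations are erased from the
#' association matrix before any training (similarities, meta-paths,
#' embeddings and classifier never see them), the classifier is trained on
#' the remaining pairs, and every miRNA is scored against the disease.
#' Candidates are returned in descending score order, ties broken by miRNA
#' index.
#'
#' @param net An `mda_network` or synthetic dataset.
#' @param disease Disease name (a column name of the association matrix).
#' @param top Number of candidates to return (`Inf` for all).
#' @param ratio Negatives per positive for classifier training.
#' @param aed_frac Optional reliable-negative threshold fraction.
#' @param encoder An [encoder_config()].
#' @param C SVM penalty factor.
#' @param seed Master seed.
#' @return Tibble with `rank`, `mirna` (name), `score`.
#' @export
rank_candidates <- function(net, disease, top = 30L, ratio = 1,
                            aed_frac = NULL, encoder = encoder_config(),
                            C = 150, seed = 1L) {
  net <- as_mda_network(net)
  j <- match(disease, colnames(net$A))
  if (is.na(j)) abort(paste0("Unknown disease: ", disease))
  A_masked <- net$A
  A_masked[, j] <- 0L
  net_masked <- net
  net_masked$A <- A_masked
  cfg <- encoder
  cfg$seed <- sub_seed(seed, 7L)
  emb <- learn_embeddings(net_masked, cfg)
  # training pairs never involve the erased disease
  pos <- positive_pairs(A_masked)
  A_for_neg <- A_masked
  A_for_neg[, j] <- 1L # excluded from the negative pool
  neg <- sample_negatives(A_for_neg, ratio = ratio, seed = sub_seed(seed, 3L))
  neg$label <- 0L
  train <- dplyr::bind_rows(pos, neg)
  if (!is.null(aed_frac)) {
    ca <- compute_cluster_aed(pair_features(emb, pos)$x,
                              pair_features(emb, neg)$x)
    kept <- aed_filter(neg, ca$distances, ca$aed, aed_frac)
    n_want <- min(round(ratio * nrow(pos)), nrow(kept))
    if (n_want < 1L) abort("AED filter left no usable training negatives.")
    set.seed(sub_seed(seed, 11L))
    kept <- kept[sample(nrow(kept), n_want), , drop = FALSE]
    train <- dplyr::bind_rows(pos, kept)
  }
  model <- train_svm(pair_features(emb, train), C = C,
                     seed = sub_seed(seed, 13L))
  cand <- tibble::tibble(mirna = seq_len(nrow(net$A)), disease = j)
  scored <- score_pairs(model, pair_features(emb, cand))
  ord <- order(-scored$score, scored$mirna)
  out <- tibble::tibble(rank = seq_along(ord),
                        mirna = rownames(net$A)[scored$mirna[ord]],
                        score = scored$score[ord])
  head(out, n = if (is.finite(top)) top else nrow(out))
}
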