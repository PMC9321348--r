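#' Generate a random disease hierarchy
#'
#' Builds a rooted random tree over `n_nodes` diseases by levels: the first
#' node is the root and every later node attaches to a uniformly chosen
#' existing node whose depth is below `depth`, preferring parents with fewer
#' than `branching` children when any are available. The result is acyclic
#' by construction.
#'
#' @param n_nodes Number of diseases (>= 1).
#' @param branching Soft cap on children per node.
#' @param depth Maximum depth (root = depth 0).
#' @param seed Integer seed.
#' @param labels Optional node names (default `d1..dn`).
#' @return A `disease_dag`.
#' @export
generate_dag <- function(n_nodes, branching = 2L, depth = 4L, seed = 1L,
                         labels = NULL) {
  stopifnot(n_nodes >= 1, branching >= 1, depth >= 1)
  labels <- labels %||% paste0("d", seq_len(n_nodes))
  stopifnot(length(labels) == n_nodes)
  set.seed(seed)
  if (n_nodes == 1L) {
    return(disease_dag(tibble::tibble(parent = character(0),
                                      child = character(0)),
                       nodes = labels))
  }
  node_depth <- c(0L, rep(NA_integer_, n_nodes - 1L))
  n_children <- integer(n_nodes)
  parent <- integer(n_nodes - 1L)
  for (i in 2:n_nodes) {
    eligible <- which(!is.na(node_depth[seq_len(i - 1L)]) &
                        node_depth[seq_len(i - 1L)] < depth)
    open <- eligible[n_children[eligible] < branching]
    pool <- if (length(open)) open else eligible
    p <- if (length(pool) == 1L) pool else sample(pool, 1L)
    parent[i - 1L] <- p
    node_depth[i] <- node_depth[p] + 1L
    n_children[p] <- n_children[p] + 1L
  }
  disease_dag(tibble::tibble(parent = labels[parent],
                             child = labels[2:n_nodes]),
              nodes = labels)
}

# calibrate the intercept of a logistic link so the mean success probability
# matches the target density
calibrate_intercept <- function(scores, density) {
  f <- function(a) mean(plogis(a + scores)) - density
  uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
}

#' Generate a synthetic heterogeneous network with planted structure
#'
#' Emulates the statistical structure the prediction method assumes: a
#' sparse binary miRNA-disease association matrix driven by shared latent
#' factors (low-rank structure), protein association matrices correlated
#' with the same factors, and a random disease hierarchy. miRNA factor
#' loadings `U` and disease loadings `V` are sparse non-negative draws;
#' associations arise from a logistic link on `U V'` with the intercept
#' calibrated so the expected density matches `density`. Observed
#' associations keep each true positive with probability `obs_frac`
#' (the held-out positives are the recoverable ground truth). Protein
#' matrices are generated the same way from `U` (resp. `V`) against their
#' own protein loadings, then corrupted by flipping each entry with
#' probability `noise`.
#'
#' @param n_m,n_d,n_p Numbers of miRNAs, diseases, proteins.
#' @param r Latent rank (`<= min(n_m, n_d)`).
#' @param density Target association density in `(0, 1)` (default 0.03,
#'   the regime of the curated human benchmark).
#' @param protein_density Target density of the protein layers.
#' @param obs_frac Probability that a true association is observed.
#' @param noise Flip probability applied to the protein matrices.
#' @param seed Integer seed; one generator drives all draws.
#' @return An `mda_synthetic` object: `A_true`, `A_obs`, `MP`, `DP`, `dag`,
#'   `U`, `V`, and the generator `params`.
#' @export
generate_network <- function(n_m = 60L, n_d = 40L, n_p = 80L, r = 4L,
                             density = 0.03, protein_density = 0.05,
                             obs_frac = 0.8, noise = 0, seed = 1L) {
  stopifnot(density > 0, density < 1, obs_frac > 0, obs_frac <= 1,
            r >= 1, r <= min(n_m, n_d), noise >= 0, noise < 0.5)
  set.seed(seed)
  sparse_factors <- function(n, r) {
    # non-negative, sparse: each entity loads on ~half the factors
    m <- matrix(rexp(n * r), n, r) * matrix(rbinom(n * r, 1L, 0.5), n, r)
    # guarantee at least one active factor per entity
    dead <- rowSums(m) == 0
    if (any(dead)) m[cbind(which(dead), sample.int(r, sum(dead), TRUE))] <- rexp(sum(dead))
    m
  }
  U <- sparse_factors(n_m, r)
  V <- sparse_factors(n_d, r)
  S <- tcrossprod(U, V)
  a0 <- calibrate_intercept(S, density)
  A_true <- matrix(rbinom(n_m * n_d, 1L, plogis(a0 + S)), n_m, n_d)
  A_obs <- A_true * matrix(rbinom(n_m * n_d, 1L, obs_frac), n_m, n_d)

  gen_layer <- function(load, n_p, dens, noise) {
    Q <- sparse_factors(n_p, ncol(load))
    Sp <- tcrossprod(load, Q)
    b0 <- calibrate_intercept(Sp, dens)
    Mx <- matrix(rbinom(length(Sp), 1L, plogis(b0 + Sp)), nrow(load), n_p)
    if (noise > 0) {
      flip <- matrix(rbinom(length(Mx), 1L, noise), nrow(Mx), ncol(Mx))
      Mx <- (Mx + flip) %% 2L
    }
    Mx
  }
  MP <- gen_layer(U, n_p, protein_density, noise)
  DP <- gen_layer(V, n_p, protein_density, noise)

  mn <- paste0("m", seq_len(n_m))
  dn <- paste0("d", seq_len(n_d))
  pn <- paste0("p", seq_len(n_p))
  dimnames(A_true) <- dimnames(A_obs) <- list(mn, dn)
  dimnames(MP) <- list(mn, pn)
  dimnames(DP) <- list(dn, pn)
  dag <- generate_dag(n_d, branching = 3L, depth = 4L,
                      seed = sub_seed(seed, 17L), labels = dn)
  structure(
    list(A_true = A_true, A_obs = A_obs, MP = MP, DP = DP, dag = dag,
         U = U, V = V,
         params = list(n_m = n_m, n_d = n_d, n_p = n_p, r = r,
                       density = density, protein_density = protein_density,
                       obs_frac = obs_frac, noise = noise, seed = seed)),
    class = "mda_synthetic"
  )
}

#' @export
print.mda_synthetic <- function(x, ...) {
  p <- x$params
  cat("<mda_synthetic> ", p$n_m, " miRNAs x ", p$n_d, " diseases x ", p$n_p,
      " proteins, rank ", p$r, "\n  observed density ",
      signif(100 * mean(x$A_obs), 3), "% (true ",
      signif(100 * mean(x$A_true), 3), "%), obs_frac ", p$obs_frac,
      ", noise ", p$noise, ", seed ", p$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset as pipeline input files
#'
#' Writes the three edge lists and the disease hierarchy in the formats read
#' by [read_edge_list()] and [read_disease_dag()], plus the full
#' ground-truth edge list for scoring held-out recovery.
#'
#' @param data An `mda_synthetic` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(data, dir) {
  stopifnot(inherits(data, "mda_synthetic"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w_edges <- function(A, path) {
    e <- adjacency_edges(A)
    writeLines(paste(e$source, e$target, sep = "\t"), path)
    path
  }
  paths <- c(
    w_edges(data$A_obs, file.path(dir, "mirna_disease.tsv")),
    w_edges(data$MP, file.path(dir, "mirna_protein.tsv")),
    w_edges(data$DP, file.path(dir, "disease_protein.tsv")),
    w_edges(data$A_true, file.path(dir, "mirna_disease_truth.tsv"))
  )
  dagp <- file.path(dir, "disease_dag.tsv")
  writeLines(paste(data$dag$edges$parent, data$dag$edges$child, sep = "\t"),
             dagp)
  invisible(c(paths, dagp))
}

#' Held-out association recovery on a synthetic network
#'
#' Trains the pipeline on the observed associations and measures how well
#' the scores separate the hidden true associations (present in `A_true`
#' but not `A_obs`) from the never-associated pairs, as a ranking AUC.
#'
#' @param data An `mda_synthetic` with `obs_frac < 1`.
#' @param encoder An [encoder_config()].
#' @param ratio,C,seed As in [cross_validate()].
#' @return List with `auc`, `aupr` and the scored held-out tibble.
#' @export
holdout_recovery <- function(data, encoder = encoder_config(), ratio = 1,
                             C = 150, seed = 1L) {
  stopifnot(inherits(data, "mda_synthetic"))
  hidden <- data$A_true == 1L & data$A_obs == 0L
  if (!any(hidden)) abort("No held-out associations (obs_frac = 1?).")
  net <- as_mda_network(data)
  cfg <- encoder
  cfg$seed <- sub_seed(seed, 7L)
  emb <- learn_embeddings(net, cfg)
  train <- pair_dataset(net$A, ratio = ratio, seed = sub_seed(seed, 3L))
  model <- train_svm(pair_features(emb, train), C = C,
                     seed = sub_seed(seed, 13L))
  # evaluation pool: all pairs unobserved in training, labeled by the truth
  eval_idx <- which(data$A_obs == 0L)
  # drop pairs that were used as training negatives
  used <- (train$disease[train$label == 0L] - 1L) * nrow(data$A_obs) +
    train$mirna[train$label == 0L]
  eval_idx <- setdiff(eval_idx, used)
  ev <- tibble::tibble(
    mirna = as.integer((eval_idx - 1L) %% nrow(data$A_obs) + 1L),
    disease = as.integer((eval_idx - 1L) %/% nrow(data$A_obs) + 1L),
    label = as.integer(data$A_true[eval_idx] == 1L)
  )
  scored <- score_pairs(model, pair_features(emb, ev))
  list(auc = roc_auc(ev$label, scored$score),
       aupr = pr_auc(ev$label, scored$score),
       scored = dplyr::bind_cols(ev, scored[c("score", "decision")]))
}
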