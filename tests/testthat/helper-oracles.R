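# Independent reference implementations used as oracles. These are written
# as literal, loop-based translations of the definitions and stay separate
# from the vectorized production code they check.

# two-hop meta-path reachability by explicit path enumeration
oracle_two_hop <- function(B) {
  n <- nrow(B)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      for (k in seq_len(ncol(B))) {
        if (B[i, k] != 0 && B[j, k] != 0) {
          out[i, j] <- 1L
          break
        }
      }
    }
  }
  out
}

# semantic contribution by enumerating every directed path ancestor -> d;
# DC(a) = max over paths of sigma^length(path)
oracle_semantic_contribution <- function(dag, d, sigma = 0.5) {
  kids <- split(dag$edges$child, dag$edges$parent)
  paths_down <- function(from, to) {
    if (from == to) return(list(character(0)))
    out <- list()
    for (ch in kids[[from]]) {
      for (p in paths_down(ch, to)) out[[length(out) + 1L]] <- c(ch, p)
    }
    out
  }
  anc <- c(d, dag_ancestors(dag, d))
  vapply(anc, function(a) {
    ps <- paths_down(a, d)
    max(vapply(ps, function(p) sigma^length(p), numeric(1)))
  }, numeric(1))
}

# per-node, loop-based neighbor attention + aggregation (one head)
oracle_gat_layer <- function(H, mask, omega, slope) {
  n <- nrow(H)
  p <- ncol(H)
  lrelu <- function(x) if (x > 0) x else slope * x
  Z <- matrix(NA_real_, n, p)
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(mask[i, ])
    e <- vapply(nb, function(j) lrelu(sum(omega * c(H[i, ], H[j, ]))),
                numeric(1))
    a <- exp(e) / sum(exp(e))
    alpha[i, nb] <- a
    agg <- rep(0, p)
    for (t in seq_along(nb)) agg <- agg + a[t] * H[nb[t], ]
    Z[i, ] <- 1 / (1 + exp(-agg))
  }
  list(alpha = alpha, Z = Z)
}

# confusion-matrix metrics straight from the definitions
oracle_confusion <- function(tp, tn, fp, fn) {
  acc <- (tp + tn) / (tp + tn + fp + fn)
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pre + sens > 0) 2 * pre * sens / (pre + sens) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  c(Acc = acc, Pre = pre, Spec = spec, Sens = sens, F1 = f1, Mcc = mcc)
}

# AUC as the (tie-corrected) Mann-Whitney U statistic
oracle_auc_mw <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  u <- 0
  for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(pos) * length(neg))
}

# tiny ready-made fixtures ------------------------------------------------

chain_dag <- function() {
  disease_dag(tibble::tibble(parent = c("r", "c"), child = c("c", "g")))
}

sibling_dag <- function() {
  disease_dag(tibble::tibble(parent = c("r", "r"), child = c("a", "b")))
}

diamond_dag <- function() {
  disease_dag(tibble::tibble(parent = c("r", "r", "x", "y"),
                             child = c("x", "y", "g", "g")))
}

# small synthetic network + cheap encoder settings shared across tests
tiny_synth <- function(seed = 42L) {
  generate_network(n_m = 14L, n_d = 10L, n_p = 12L, r = 2L, density = 0.2,
                   protein_density = 0.2, obs_frac = 0.9, seed = seed)
}

tiny_encoder <- function(epochs = 25L, seed = 7L) {
  encoder_config(head_dim = 4L, n_heads = 2L, module_attn_dim = 6L,
                 epochs = epochs, seed = seed)
}

# linearly separable two-cluster toy in pair-feature form
separable_toy <- function(n_per_class = 10L, d = 4L, sep = 30L, seed = 3L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}
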