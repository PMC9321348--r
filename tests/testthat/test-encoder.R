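test_that("feature projection is the plain linear map", {
  X <- rbind(c(2, 3))
  expect_equal(project_features(X, diag(2)), X)
  expect_equal(project_features(X, matrix(0, 2, 2)), matrix(0, 1, 2))
  expect_equal(project_features(X, matrix(c(1, 1), 2, 1)), matrix(5, 1, 1))
  expect_error(project_features(X, diag(3)), "shapes")
})

test_that("attention softmax normalizes over the neighbor set", {
  H <- rbind(c(1, 0), c(0, 1), c(1, 1))
  # single neighbor: weight exactly 1
  mask1 <- diag(3) > 0
  a1 <- attention_scores(H, mask1, rep(0.3, 4))
  expect_equal(unname(diag(a1)), rep(1, 3))
  # equal scores: uniform weights
  mask <- matrix(TRUE, 3, 3)
  a2 <- attention_scores(H, mask, rep(0, 4))
  expect_equal(unname(a2), matrix(1 / 3, 3, 3))
  # closed-form two-neighbor case: e = (ln 2, 0) -> (2/3, 1/3)
  H2 <- rbind(c(log(2)), c(0))
  a3 <- attention_scores(H2, matrix(TRUE, 2, 2), c(0, 1))
  expect_equal(unname(a3[1, ]), c(2 / 3, 1 / 3))
  expect_equal(rowSums(a3), rep(1, 2), ignore_attr = TRUE)
  expect_error(attention_scores(H, matrix(FALSE, 3, 3), rep(0, 4)), "neighbor")
})

test_that("aggregation applies the logistic to the attention-weighted sum", {
  # all-zero latent features -> every coordinate sigma(0) = 0.5
  Z <- aggregate_neighbors(matrix(1, 1, 1), matrix(0, 1, 3))
  expect_equal(unname(Z), matrix(0.5, 1, 3))
  # large positive neighbor saturates toward 1
  Zs <- aggregate_neighbors(matrix(1, 1, 1), matrix(50, 1, 1))
  expect_gt(Zs[1, 1], 0.999999)
  # hand case: alpha (.5, .5), h = 2 and 0 -> sigma(1)
  Zh <- aggregate_neighbors(matrix(c(0.5, 0.5), 1), rbind(2, 0))
  expect_equal(Zh[1, 1], plogis(1))
})

test_that("one attention head reproduces a dense per-node reference", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    p <- sample(2:4, 1)
    H <- matrix(rnorm(n * p), n, p)
    mask <- matrix(runif(n * n) < 0.5, n, n)
    diag(mask) <- TRUE
    omega <- rnorm(2 * p)
    alpha <- attention_scores(H, mask, omega, leaky_slope = 0.2)
    Z <- aggregate_neighbors(alpha, H)
    ref <- oracle_gat_layer(H, mask, omega, 0.2)
    expect_equal(alpha, ref$alpha, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(Z, ref$Z, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("module attention returns convex weights with closed-form softmax", {
  set.seed(52)
  z <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(6 * 3), 6, 3)
  eps <- rnorm(6)
  lambda <- rnorm(6)
  # identical modules -> uniform beta and unchanged embedding
  f <- module_attention(list(z, z, z), W, eps, lambda)
  expect_equal(f$beta, rep(1 / 3, 3))
  expect_equal(f$Z, z)
  # single module -> beta 1
  f1 <- module_attention(list(z), W, eps, lambda)
  expect_equal(f1$beta, 1)
  expect_equal(f1$Z, z)
  # closed form: importances (ln 3, 0) -> beta (0.75, 0.25)
  expect_equal(hetmda:::softmax_vec(c(log(3), 0)), c(0.75, 0.25))
  # convexity: fused embedding within per-coordinate min/max of modules
  z2 <- matrix(rnorm(12), 4, 3)
  f2 <- module_attention(list(z, z2), W, eps, lambda)
  expect_equal(sum(f2$beta), 1)
  lo <- pmin(z, z2); hi <- pmax(z, z2)
  expect_true(all(f2$Z >= lo - 1e-12 & f2$Z <= hi + 1e-12))
})

test_that("reconstruction loss matches the cross-entropy closed forms", {
  expect_equal(cross_entropy(1, 0.5), log(2))
  expect_equal(cross_entropy(c(1, 0), c(0.8, 0.2)), -log(0.8))
  expect_lt(cross_entropy(c(1, 0), c(1, 0)), 1e-5)
  # inner-product decoder route
  Z_m <- matrix(0, 1, 2)
  Z_d <- matrix(0, 1, 2)
  expect_equal(reconstruction_loss(Z_m, Z_d, matrix(1, 1, 1)), log(2))
})

test_that("analytic gradients match finite differences", {
  syn <- tiny_synth()
  net <- mda_network(syn$A_obs, syn$MP, syn$DP, syn$dag)
  sims <- integrated_similarities(net$A, net$dag)
  mods <- build_modules(net$A, sims$MS, sims$DS, net$MP, net$DP)
  cfg <- tiny_encoder(epochs = 0L)
  Xs <- lapply(mods, function(m) m$values)
  masks <- lapply(mods, function(m) m$values > 0)
  n <- nrow(Xs[[1]])
  set.seed(cfg$seed)
  params <- hetmda:::init_encoder_params(n, 3L, cfg)
  lg <- hetmda:::gat_loss_and_grads(Xs, masks, nrow(net$A), net$A, params, cfg)

  set_leaf <- function(tree, path, val) {
    if (length(path) == 1L) tree[[path[[1]]]] <- val
    else tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], val)
    tree
  }
  loss_at <- function(p) {
    hetmda:::gat_loss_and_grads(Xs, masks, nrow(net$A), net$A, p, cfg)$loss
  }
  check_leaf <- function(path, arr, garr) {
    idxs <- unique(round(seq(1, length(arr), length.out = min(3, length(arr)))))
    for (i in idxs) {
      h <- 1e-6
      up <- arr; up[i] <- up[i] + h
      dn <- arr; dn[i] <- dn[i] - h
      num <- (loss_at(set_leaf(params, path, up)) -
                loss_at(set_leaf(params, path, dn))) / (2 * h)
      expect_equal(garr[i], num, tolerance = 1e-4)
    }
  }
  walk <- function(tree, gtree, path = list()) {
    if (is.list(tree)) {
      for (k in seq_along(tree)) {
        key <- if (!is.null(names(tree))) names(tree)[k] else k
        walk(tree[[k]], gtree[[k]], c(path, list(key)))
      }
    } else check_leaf(path, tree, gtree)
  }
  walk(params, lg$grads)
})

test_that("pretraining reduces the loss, is seed-deterministic, logs finitely", {
  syn <- tiny_synth()
  net <- mda_network(syn$A_obs, syn$MP, syn$DP, syn$dag)
  sims <- integrated_similarities(net$A, net$dag)
  mods <- build_modules(net$A, sims$MS, sims$DS, net$MP, net$DP)

  emb0 <- pretrain_embeddings(mods, net$A, tiny_encoder(epochs = 0L))
  emb <- pretrain_embeddings(mods, net$A, tiny_encoder(epochs = 60L))
  expect_lt(emb$final_loss, emb0$final_loss)
  expect_true(all(is.finite(emb$trajectory$loss)))
  expect_true(all(is.finite(emb$Z_m)) && all(is.finite(emb$Z_d)))
  expect_equal(nrow(emb$Z_m), nrow(net$A))
  expect_equal(nrow(emb$Z_d), ncol(net$A))
  expect_equal(ncol(emb$Z_m), tiny_encoder()$dim)

  # attention normalization carried through: per-type module weights sum to 1
  expect_equal(sum(emb$beta$miRNA), 1, tolerance = 1e-6)
  expect_equal(sum(emb$beta$disease), 1, tolerance = 1e-6)

  # bitwise determinism under a fixed seed
  emb2 <- pretrain_embeddings(mods, net$A, tiny_encoder(epochs = 60L))
  expect_identical(emb$trajectory, emb2$trajectory)
  expect_identical(emb$Z_m, emb2$Z_m)

  # epochs = 0 embeddings are deterministic given the seed
  emb0b <- pretrain_embeddings(mods, net$A, tiny_encoder(epochs = 0L))
  expect_identical(emb0$Z_m, emb0b$Z_m)
})

test_that("embeddings are invariant to edge-list input order", {
  syn <- tiny_synth()
  e <- adjacency_edges(syn$A_obs)
  set.seed(61)
  e_shuf <- e[sample(nrow(e)), ]
  A1 <- build_adjacency(e, rownames(syn$A_obs), colnames(syn$A_obs))
  A2 <- build_adjacency(e_shuf, rownames(syn$A_obs), colnames(syn$A_obs))
  expect_identical(A1, A2)
  net1 <- mda_network(A1, syn$MP, syn$DP, syn$dag)
  net2 <- mda_network(A2, syn$MP, syn$DP, syn$dag)
  cfg <- tiny_encoder(epochs = 10L)
  expect_identical(learn_embeddings(net1, cfg)$Z_m,
                   learn_embeddings(net2, cfg)$Z_m)
})
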