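test_that("GIP bandwidth follows the reciprocal mean-squared-norm rule", {
  expect_equal(gip_bandwidth(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(gip_bandwidth(matrix(c(1, 1, 1, 1), 1)), 1 / 4)
  expect_error(gip_bandwidth(matrix(0, 1, 2)), "zero")
})

test_that("GIP kernel matches the closed form and is a valid similarity", {
  S <- gip_kernel(rbind(c(1, 0), c(0, 1)))
  expect_equal(S[1, 2], exp(-2))
  expect_equal(diag(S), rep(1, 2), ignore_attr = TRUE)

  set.seed(11)
  for (rep in 1:10) {
    P <- matrix(rbinom(8 * 5, 1, 0.4), 8, 5)
    if (sum(P) == 0) P[1, 1] <- 1
    S <- gip_kernel(P)
    expect_equal(S, t(S))
    expect_true(all(S > 0 & S <= 1))
    expect_equal(diag(S), rep(1, 8), ignore_attr = TRUE)
    # identical profiles get similarity exactly 1
    P2 <- rbind(P[1, ], P[1, ])
    expect_equal(gip_kernel(P2)[1, 2], 1)
  }
})

test_that("semantic contribution decays along the hierarchy as specified", {
  dc <- semantic_contribution(chain_dag(), "g")
  expect_equal(dc[c("g", "c", "r")], c(g = 1, c = 0.5, r = 0.25))
  expect_equal(semantic_value(dc), 1.75)

  expect_equal(semantic_contribution(sibling_dag(), "r"), c(r = 1))

  dcd <- semantic_contribution(diamond_dag(), "g")
  expect_equal(dcd[["r"]], 0.25)
  expect_equal(semantic_value(dcd), 2.25)

  expect_error(semantic_contribution(chain_dag(), "zz"), "Unknown")
})

test_that("semantic contribution agrees with path-enumeration oracle", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    # random DAG: each node gets 1-2 parents among earlier nodes
    edges <- dplyr::bind_rows(lapply(2:n, function(i) {
      np <- sample(1:min(2L, i - 1L), 1)
      tibble::tibble(parent = paste0("n", sample(i - 1L, np)),
                     child = paste0("n", i))
    }))
    dag <- disease_dag(edges)
    d <- paste0("n", sample(n, 1))
    dc <- semantic_contribution(dag, d)
    oc <- oracle_semantic_contribution(dag, d)
    expect_equal(dc[order(names(dc))], oc[order(names(oc))])
  }
})

test_that("semantic similarity matches hand-computed cases and properties", {
  expect_equal(semantic_similarity(sibling_dag(), "a", "b"), 1 / 3)
  expect_equal(semantic_similarity(chain_dag(), "c", "g"), 2.25 / 3.25)
  for (d in c("r", "c", "g")) {
    expect_equal(semantic_similarity(chain_dag(), d, d), 1)
  }
  # disjoint hierarchies: similarity 0
  two_trees <- disease_dag(tibble::tibble(parent = c("r1", "r2"),
                                          child = c("a", "b")))
  S <- semantic_similarity_matrix(two_trees, c("a", "b", "r1", "r2"))
  expect_equal(S["a", "b"], 0)
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 4), ignore_attr = TRUE)
  expect_equal(S["a", "r1"], semantic_similarity(two_trees, "a", "r1"))
})

test_that("miRNA functional similarity is the best-match average", {
  dag <- sibling_dag()
  SS <- semantic_similarity_matrix(dag, c("a", "b"))
  # identical single-disease sets -> similarity 1
  A <- rbind(m1 = c(1, 0), m2 = c(1, 0))
  colnames(A) <- c("a", "b")
  expect_equal(mirna_functional_similarity(A, SS)[1, 2], 1)
  # disjoint singletons -> the cross semantic similarity (1/3)
  A2 <- rbind(m1 = c(1, 0), m2 = c(0, 1))
  colnames(A2) <- c("a", "b")
  expect_equal(mirna_functional_similarity(A2, SS)[1, 2], 1 / 3)
  # empty disease set -> undefined entry
  A3 <- rbind(m1 = c(1, 0), m2 = c(0, 0))
  colnames(A3) <- c("a", "b")
  FS <- mirna_functional_similarity(A3, SS)
  expect_true(is.na(FS[1, 2]))
  expect_true(is.na(FS[2, 2]))

  # symmetry and range on random inputs
  set.seed(31)
  dag2 <- generate_dag(6, seed = 5)
  SS2 <- semantic_similarity_matrix(dag2, paste0("d", 1:6))
  for (rep in 1:10) {
    A4 <- matrix(rbinom(5 * 6, 1, 0.5), 5, 6,
                 dimnames = list(paste0("m", 1:5), paste0("d", 1:6)))
    FS4 <- mirna_functional_similarity(A4, SS2)
    expect_equal(FS4, t(FS4))
    expect_true(all(is.na(FS4) | (FS4 >= 0 & FS4 <= 1)))
  }
})

test_that("integration fills undefined entries from the fallback", {
  fb <- rbind(c(1, 0.1353), c(0.1353, 1))
  allna <- matrix(NA_real_, 2, 2)
  expect_equal(integrate_similarity(allna, fb), fb)

  prim <- rbind(c(1, 0.9), c(0.9, 1))
  expect_equal(integrate_similarity(prim, fb), prim)

  mixed <- rbind(c(1, NA), c(NA, 1))
  out <- integrate_similarity(mixed, fb)
  expect_equal(out[1, 2], 0.1353)
  expect_false(anyNA(out))
  expect_equal(diag(out), c(1, 1))
  expect_error(integrate_similarity(matrix(1, 1, 1), fb), "shape")
})

test_that("integrated similarities on a network are well-formed", {
  syn <- tiny_synth()
  sims <- integrated_similarities(syn$A_obs, syn$dag)
  for (S in sims) {
    expect_false(anyNA(S))
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(S, t(S), tolerance = 1e-10)
    expect_equal(unname(diag(S)), rep(1, nrow(S)))
  }
})
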