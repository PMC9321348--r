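test_that("confusion metrics match the exhaustive tuple oracle", {
  # closed-form case
  m <- hetmda:::confusion_metrics(40, 30, 20, 10)
  expect_equal(m$Acc, 0.7)
  expect_equal(m$Pre, 2 / 3)
  expect_equal(m$Sens, 0.8)
  expect_equal(m$Spec, 0.6)
  expect_equal(m$F1, 0.72727, tolerance = 1e-4)
  expect_equal(m$Mcc, 0.40825, tolerance = 1e-4)

  for (tp in 0:10) for (tn in c(0L, 3L, 10L)) for (fp in c(0L, 2L, 7L)) {
    for (fn in c(0L, 5L)) {
      got <- hetmda:::confusion_metrics(tp, tn, fp, fn)
      want <- oracle_confusion(tp, tn, fp, fn)
      expect_equal(unlist(got), want, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("compute_metrics counts at the threshold and bounds hold", {
  lab <- c(1, 1, 0, 0)
  sc <- c(0.9, 0.4, 0.6, 0.1)
  m <- compute_metrics(lab, sc, threshold = 0.5)
  expect_equal(unlist(m[c("TP", "TN", "FP", "FN")]),
               c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(m$TP + m$FN, sum(lab))
  expect_equal(m$TN + m$FP, sum(lab == 0))

  perfect <- compute_metrics(rep(c(1, 0), each = 50),
                             rep(c(0.9, 0.1), each = 50))
  expect_equal(perfect$Acc, 1)
  expect_equal(perfect$F1, 1)
  expect_equal(perfect$Mcc, 1)
  expect_equal(perfect$AUC, 1)
  expect_equal(perfect$AUPR, 1)

  expect_equal(compute_metrics(c(1, 0), c(0.9, 0.1))$AUC, 1)
  expect_error(compute_metrics(c(1, 1), c(0.5, 0.6)), "both classes")
})

test_that("AUC equals the Mann-Whitney statistic, with and without ties", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(10:100, 1)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) next
    sc <- sample(round(runif(n), 2)) # rounding induces ties
    expect_equal(roc_auc(lab, sc), oracle_auc_mw(lab, sc), tolerance = 1e-12)
  }
})

test_that("AUC and AUPR agree with an established reference", {
  skip_if_not_installed("pROC")
  set.seed(92)
  lab <- rbinom(60, 1, 0.4)
  sc <- runif(60)
  ref <- as.numeric(suppressMessages(pROC::auc(lab, sc, direction = "<")))
  expect_equal(roc_auc(lab, sc), ref, tolerance = 1e-10)
})

test_that("stratified folds partition the data and preserve class ratio", {
  set.seed(93)
  lab <- rep(c(1L, 0L), c(50, 50))
  set.seed(94)
  fold <- hetmda:::stratified_folds(lab, 5)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 100L)
  for (f in 1:5) {
    expect_equal(sum(fold == f), 20L)
    expect_equal(sum(fold == f & lab == 1L), 10L)
  }
  # imbalanced classes: within one sample of proportionality
  lab2 <- rep(c(1L, 0L), c(23, 40))
  set.seed(95)
  fold2 <- hetmda:::stratified_folds(lab2, 5)
  tab <- table(fold2, lab2)
  expect_true(max(tab[, "1"]) - min(tab[, "1"]) <= 1)
  expect_true(max(tab[, "0"]) - min(tab[, "0"]) <= 1)
  expect_error(hetmda:::stratified_folds(c(1L, rep(0L, 9)), 5), "fewer")
})

test_that("cross-validation reports fold metrics and is seed-deterministic", {
  syn <- tiny_synth()
  cfg <- tiny_encoder(epochs = 15L)
  cv <- cross_validate(syn, k = 3, repeats = 1, encoder = cfg, seed = 5)
  expect_s3_class(cv, "mda_cv")
  expect_equal(nrow(cv$folds), 3L)
  expect_true(all(cv$folds$AUC >= 0 & cv$folds$AUC <= 1))
  expect_true(all(c("Acc", "Pre", "Spec", "Sens", "F1", "Mcc", "AUC", "AUPR")
                  %in% names(cv$folds)))
  # folds partition the pair set
  expect_equal(sum(cv$folds$TP + cv$folds$TN + cv$folds$FP + cv$folds$FN),
               2L * sum(syn$A_obs))

  cv2 <- cross_validate(syn, k = 3, repeats = 1, encoder = cfg, seed = 5)
  expect_identical(glance(cv), glance(cv2))
  expect_identical(cv$folds, cv2$folds)

  g <- glance(cv)
  expect_equal(nrow(g), 1L)
  expect_true(all(is.finite(unlist(g))))
})

test_that("report files are written and the JSON summary is stable", {
  syn <- tiny_synth()
  cv <- cross_validate(syn, k = 3, encoder = tiny_encoder(epochs = 10L),
                       seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_cv_report(cv, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$mean$AUC, cv$summary$mean[cv$summary$metric == "AUC"])
  folds <- utils::read.csv(paths[["csv"]])
  expect_equal(nrow(folds), nrow(cv$folds))
})

test_that("parameter sweeps vary exactly the requested knob", {
  syn <- tiny_synth()
  cfg <- tiny_encoder(epochs = 8L)
  sw <- sweep_parameter(syn, "ratio", c(1, 2), k = 3, encoder = cfg, seed = 3)
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$ratio, c(1, 2))
  expect_true(all(is.finite(sw$AUC)))

  swd <- sweep_parameter(syn, "dimension", c(4, 8), k = 3, encoder = cfg,
                         seed = 3)
  expect_equal(swd$dimension, c(4, 8))
})

test_that("case-study ranking erases the disease before training", {
  syn <- tiny_synth()
  net <- hetmda:::as_mda_network(syn)
  target <- colnames(net$A)[which.max(colSums(net$A))]
  rk <- rank_candidates(syn, target, top = Inf,
                        encoder = tiny_encoder(epochs = 25L), seed = 4)
  expect_equal(nrow(rk), nrow(net$A))
  expect_equal(rk$rank, seq_len(nrow(net$A)))
  expect_true(all(diff(rk$score) <= 1e-12))
  # erased true partners rank better than the random-expectation midpoint
  truth <- rownames(net$A)[net$A[, target] == 1]
  expect_gt(length(truth), 1)
  mean_rank <- mean(rk$rank[rk$mirna %in% truth])
  expect_lt(mean_rank, (nrow(net$A) + 1) / 2)
  expect_error(rank_candidates(syn, "no-such-disease"), "Unknown disease")
})
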