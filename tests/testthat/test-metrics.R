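# Metrics: hand-worked examples, invariance properties, and agreement
# with independent oracles.

test_that("confusion matrix tallies correctly", {
  cm <- confusion(c(0, 1, 2), c(0, 2, 2), 3)
  expect_equal(unname(diag(cm)), c(1, 0, 1))
  expect_equal(unname(cm[2, 3]), 1)
  expect_equal(unname(rowSums(cm)), c(1, 1, 1))

  cmp <- confusion(0:2, 0:2, 3)
  expect_true(all(cmp[upper.tri(cmp) | lower.tri(cmp)] == 0))
  expect_error(confusion(c(0, 5), c(0, 1), 3), "labels")
})

test_that("accuracy, micro and macro averages match hand computations", {
  cm <- confusion(c(rep(0, 6), rep(1, 8), rep(2, 6)),
                  c(0, 0, 0, 0, 0, 1,  0, 1, 1, 1, 1, 1, 1, 2,  1, 2, 2, 2, 2, 2), 3)
  expect_equal(unclass(cm)[1, ], c(`0` = 5, `1` = 1, `2` = 0), ignore_attr = TRUE)
  expect_equal(accuracy(cm), 16 / 20)
  mic <- precision_recall_micro(cm)
  expect_equal(unname(mic), c(0.8, 0.8))
  mac <- precision_recall_macro(cm)
  expect_equal(unname(mac["precision"]), (5 / 6 + 6 / 8 + 5 / 6) / 3)

  d <- confusion(0:1, 0:1, 2)
  expect_equal(accuracy(d), 1)
  off <- confusion(c(0, 1), c(1, 0), 2)
  expect_equal(accuracy(off), 0)
  b <- matrix(c(5, 2, 1, 4), 2, 2, byrow = TRUE)
  class(b) <- c("confusion_matrix", class(b))
  expect_equal(accuracy(b), 9 / 12)
})

test_that("F1 follows the harmonic mean with the zero convention", {
  expect_equal(f1(1, 1), 1)
  expect_equal(f1(1, 0), 0)
  expect_equal(f1(0.5, 1), 2 / 3)
  expect_equal(f1(0, 0), 0)
})

test_that("MCC endpoints, binary reduction and permutation invariance", {
  expect_equal(mcc(confusion(c(0, 1, 2, 0), c(0, 1, 2, 0), 3)), 1)
  expect_equal(mcc(confusion(c(0, 0, 1, 1), c(1, 1, 0, 0), 2)), -1)

  # binary covariance form reduces to the printed formula
  set.seed(20)
  true <- sample(0:1, 50, replace = TRUE)
  pred <- ifelse(runif(50) < 0.7, true, 1 - true)
  cm <- confusion(true, pred, 2)
  tp <- cm[2, 2]; tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]
  printed <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(mcc(cm), printed, tolerance = 1e-12)

  # simultaneous row/column permutation leaves MCC unchanged
  true3 <- sample(0:2, 60, replace = TRUE)
  pred3 <- sample(0:2, 60, replace = TRUE)
  m1 <- mcc(confusion(true3, pred3, 3))
  perm <- c(2L, 0L, 1L)
  m2 <- mcc(confusion(perm[true3 + 1], perm[pred3 + 1], 3))
  expect_equal(m1, m2, tolerance = 1e-12)

  expect_equal(mcc(confusion(c(0, 0), c(0, 0), 2)), 0)  # degenerate -> 0
})

test_that("micro precision = micro recall = accuracy on random confusion matrices", {
  set.seed(21)
  for (i in 1:1000) {
    K <- sample(2:5, 1)
    n <- sample(5:40, 1)
    true <- sample(0:(K - 1), n, replace = TRUE)
    pred <- sample(0:(K - 1), n, replace = TRUE)
    cm <- confusion(true, pred, K)
    mic <- suppressWarnings(precision_recall_micro(cm))
    expect_identical(unname(mic["precision"]), unname(mic["recall"]))
    expect_equal(unname(mic["precision"]), accuracy(cm), tolerance = 1e-12)
  }
})

test_that("all metrics agree with independent oracles on 100 random triples", {
  set.seed(22)
  for (i in 1:100) {
    tr <- rand_triple()
    rep <- suppressWarnings(metrics_report(tr$true, tr$pred, tr$scores, K = 3))
    expect_equal(rep$accuracy, o_accuracy(tr$true, tr$pred), tolerance = 1e-10)
    mic <- o_micro(tr$true, tr$pred, 3)
    mac <- o_macro(tr$true, tr$pred, 3)
    expect_equal(rep$precision_micro, unname(mic["precision"]), tolerance = 1e-10)
    expect_equal(rep$recall_micro, unname(mic["recall"]), tolerance = 1e-10)
    expect_equal(rep$precision_macro, unname(mac["precision"]), tolerance = 1e-10)
    expect_equal(rep$recall_macro, unname(mac["recall"]), tolerance = 1e-10)
    expect_equal(rep$mcc, o_mcc(tr$true, tr$pred, 3), tolerance = 1e-10)
    for (k in 1:3) {
      y <- as.integer(tr$true == (k - 1))
      expect_equal(rep$per_class$roc_auc[k], o_roc_auc(y, tr$scores[, k]),
                   tolerance = 1e-10)
      expect_equal(rep$per_class$pr_auc[k], o_pr_auc(y, tr$scores[, k]),
                   tolerance = 1e-10)
    }
  }
})

test_that("ROC/PR curves match hand-worked and limiting cases", {
  # 4 samples, scores (0.9, 0.8, 0.4, 0.1), labels (1, 0, 1, 0) -> AUC 0.75
  cur <- roc_pr_curves(list(true_labels = c(1, 0, 1, 0),
                            scores = cbind(1 - c(0.9, 0.8, 0.4, 0.1),
                                           c(0.9, 0.8, 0.4, 0.1))))
  expect_equal(cur$per_class$roc_auc[2], 0.75)

  # perfectly separating scores -> all AUCs 1
  true <- rep(0:2, each = 4)
  scores <- t(sapply(true, function(k) { v <- c(0.1, 0.1, 0.1); v[k + 1] <- 0.8; v }))
  cur2 <- roc_pr_curves(list(true_labels = true, scores = scores))
  expect_true(all(cur2$per_class$roc_auc == 1))
  expect_true(all(cur2$per_class$pr_auc == 1))
  expect_equal(cur2$micro$roc_auc, 1)

  # label-independent scores, large n -> AUC ~ 0.5
  set.seed(23)
  n <- 10000
  true <- sample(0:1, n, replace = TRUE)
  s <- runif(n)
  cur3 <- roc_pr_curves(list(true_labels = true, scores = cbind(1 - s, s)))
  expect_equal(cur3$per_class$roc_auc[2], 0.5, tolerance = 0.02)

  # AUC invariant under strictly monotone score transforms
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  s8 <- c(0.9, 0.6, 0.8, 0.55, 0.3, 0.5, 0.2, 0.1)
  a1 <- sparcnet:::binary_curves(y, s8)$roc_auc
  a2 <- sparcnet:::binary_curves(y, exp(5 * s8))$roc_auc
  expect_equal(a1, a2)

  # a class without positives is skipped with a warning
  expect_warning(
    out <- roc_pr_curves(list(true_labels = c(0, 0, 1, 1),
                              scores = matrix(runif(12), 4, 3))),
    "no positive")
  expect_true(is.na(out$per_class$roc_auc[3]))
})

test_that("metrics reports serialise to CSV/JSON", {
  set.seed(24)
  tr <- rand_triple()
  rep <- suppressWarnings(metrics_report(tr$true, tr$pred, tr$scores, K = 3))
  pre <- file.path(tempdir(), "mtest")
  paths <- write_metrics_report(rep, pre)
  expect_true(all(file.exists(paths)))
  j <- jsonlite::read_json(paths[1])
  expect_equal(j$accuracy, rep$accuracy, tolerance = 1e-12)
})
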