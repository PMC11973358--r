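# Experimental protocol: folds, training loop, search, external test.

test_that("stratified folds partition with per-class balance, deterministically", {
  labels <- rep(0:4, each = 20)
  sp <- stratified_kfold(labels, 5, seed = 3)
  expect_equal(unname(table(sp$assignments)), rep(20L, 5), ignore_attr = TRUE)
  for (cl in 0:4) {
    per <- table(sp$assignments[labels == cl])
    expect_true(max(per) - min(per) <= 1)
  }
  sp2 <- stratified_kfold(labels, 5, seed = 3)
  expect_identical(sp$assignments, sp2$assignments)
  sp3 <- stratified_kfold(labels, 5, seed = 4)
  expect_false(identical(sp$assignments, sp3$assignments))

  bad <- c(rep(0, 90), rep(1, 9), 2)
  expect_error(stratified_kfold(bad, 5), "2")   # the 1-sample class is named
})

test_that("train_model learns a separable toy problem and stops early", {
  ds <- separable_images(n_per = 8, size = 32, seed = 50)
  x <- sparcnet:::images_to_batch(ds$images)
  n <- length(ds$labels)
  tr <- sort(c(seq(1, n, by = 4), seq(2, n, by = 4)))   # both classes
  va <- setdiff(seq_len(n), tr)
  cfg <- arch_config("baseline", num_classes = 2L, input_size = 32L,
                     stage_depths = c(1L, 1L, 1L, 1L), base_width = 4L)
  tcfg <- train_config(learning_rate = 2e-3, batch_size = 8L, max_epochs = 15L,
                       patience = 14L, seed = 2L)
  fit <- train_model(cfg, tcfg, x[, , , tr, drop = FALSE], ds$labels[tr],
                     x[, , , va, drop = FALSE], ds$labels[va],
                     stop_on_val_accuracy = 1)
  expect_lte(nrow(fit$history), 15)
  expect_equal(max(fit$history$val_accuracy), 1)

  # early stopping: with a vanishing learning rate only the running
  # normalisation statistics drift, so improvement soon stalls and the
  # loop must halt exactly `patience` epochs after the best one
  tc0 <- train_config(learning_rate = 1e-30, batch_size = 8L, max_epochs = 10L,
                      patience = 1L, seed = 2L)
  fit0 <- suppressWarnings(
    train_model(cfg, tc0, x[, , , tr, drop = FALSE], ds$labels[tr],
                x[, , , va, drop = FALSE], ds$labels[va]))
  expect_lt(nrow(fit0$history), 10)
  expect_equal(nrow(fit0$history), fit0$best_epoch + 1L)
})

test_that("per-epoch history is consistent with the returned reports", {
  ds <- separable_images(n_per = 6, size = 32, seed = 51)
  x <- sparcnet:::images_to_batch(ds$images)
  cfg <- arch_config("baseline", num_classes = 2L, input_size = 32L,
                     stage_depths = c(1L, 1L, 1L, 1L), base_width = 4L)
  tcfg <- train_config(batch_size = 6L, max_epochs = 4L, patience = 3L, seed = 9L)
  cv <- cross_validate(cfg, tcfg, x, ds$labels, k = 2L, seed = 1L)
  expect_length(cv$folds, 2)
  accs <- vapply(cv$folds, function(f) f$report$accuracy, numeric(1))
  expect_true(cv$summary$mean[1] >= min(accs) && cv$summary$mean[1] <= max(accs))
  # identical seed reproduces the fold assignment
  cv_split <- stratified_kfold(ds$labels, 2L, seed = 1L)
  expect_identical(cv$split$assignments, cv_split$assignments)
  # history rows carry the full metric set
  expect_true(all(c("val_accuracy", "val_mcc", "val_f1_macro") %in%
                    names(cv$folds[[1]]$history)))
})

test_that("hyperparameter search is exhaustive over grids, seeded, argmax-correct", {
  # deterministic stub objective: prefers lr near 1e-2
  obj <- function(tc) -abs(log10(tc$learning_rate) + 2)
  one <- hyperparameter_search(list(grid = list(learning_rate = 0.5)), obj)
  expect_equal(one$best$learning_rate, 0.5)
  expect_equal(nrow(one$trials), 1)

  space <- list(grid = list(learning_rate = c(1e-4, 1e-3, 1e-2),
                            batch_size = c(8, 16)),
                random = list(learning_rate = structure(c(1e-4, 1e-1), log = TRUE)),
                budget = 10L)
  s1 <- hyperparameter_search(space, obj, seed = 6)
  s2 <- hyperparameter_search(space, obj, seed = 6)
  expect_equal(s1$trials, s2$trials)
  expect_equal(nrow(s1$trials), 10)            # 6 grid + 4 random
  expect_gte(s1$best_score, max(s1$trials$score) - 1e-12)
  expect_equal(s1$best$learning_rate, s1$trials$learning_rate[which.max(s1$trials$score)])

  expect_error(hyperparameter_search(list(budget = 3L), obj), "empty")
})

test_that("external test guards against leakage and evaluates cleanly", {
  ds <- separable_images(n_per = 6, size = 32, seed = 52)
  x <- sparcnet:::images_to_batch(ds$images)
  cfg <- arch_config("baseline", num_classes = 2L, input_size = 32L,
                     stage_depths = c(1L, 1L, 1L, 1L), base_width = 4L)
  tcfg <- train_config(batch_size = 6L, max_epochs = 6L, patience = 5L, seed = 3L)
  tr <- 1:8; te <- 9:12
  fit <- train_model(cfg, tcfg, x[, , , tr, drop = FALSE], ds$labels[tr],
                     x[, , , te, drop = FALSE], ds$labels[te],
                     stop_on_val_accuracy = 1)
  trp <- sprintf("/data/train/img%02d.png", tr)
  rep <- external_test(fit$model, x[, , , te, drop = FALSE], ds$labels[te],
                       test_paths = sprintf("/data/test/img%02d.png", te),
                       train_paths = trp)
  expect_s3_class(rep$confusion, "confusion_matrix")
  expect_true(all(c("precision", "recall", "f1", "roc_auc", "pr_auc") %in%
                    names(rep$per_class)))
  expect_error(
    external_test(fit$model, x[, , , te, drop = FALSE], ds$labels[te],
                  test_paths = trp[1], train_paths = trp),
    "leakage")
})
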