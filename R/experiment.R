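# Experimental protocol: stratified k-fold cross-validation, the
# training loop with early stopping, random+grid hyperparameter search,
# and leakage-guarded external testing.

#' Training configuration
#'
#' @param learning_rate positive step size.
#' @param batch_size mini-batch size.
#' @param weight_decay decoupled weight-decay coefficient (>= 0).
#' @param max_epochs epoch budget (default 100, the protocol's
#'   iteration count).
#' @param patience early-stopping patience in epochs (must be smaller
#'   than `max_epochs`); validation loss is the monitored quantity.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed RNG seed for shuffling/augmentation/initialisation.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         weight_decay = 0, max_epochs = 100L, patience = 10L,
                         optimizer = c("adam", "sgd"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (weight_decay < 0) stopf("weight_decay must be >= 0")
  if (patience >= max_epochs) stopf("patience must be smaller than max_epochs")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class (deterministically given `seed`) and deals
#' samples round-robin into folds, so per-class fold sizes differ by at
#' most one.
#'
#' @param labels per-sample class labels.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return a `fold_split`: list with `k` and per-sample `assignments`
#'   in `1:k`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.vector(labels)
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small))
    stopf("class(es) %s have fewer than k = %d samples",
          paste(small, collapse = ", "), k)
  assignments <- integer(length(labels))
  set.seed(seed)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    assignments[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(k = as.integer(k), assignments = assignments),
            class = "fold_split")
}

eval_model <- function(model, x, labels, batch = 32L) {
  n <- dim(x)[4]
  logits <- matrix(0, model$cfg$num_classes, n)
  loss <- 0
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1, n)
    lg <- network_forward_full(model, x[, , , idx, drop = FALSE],
                               training = FALSE)$logits
    logits[, idx] <- lg
    loss <- loss + cross_entropy(lg, labels[idx] + 1L)$loss * length(idx)
  }
  probs <- t(softmax_cols(logits))
  pred <- max.col(t(logits), ties.method = "first") - 1L
  list(loss = loss / n, probs = probs, pred = pred,
       report = suppressWarnings(metrics_report(labels, pred, probs,
                                                K = model$cfg$num_classes)))
}

#' Train a model with early stopping
#'
#' Minimises categorical cross-entropy by mini-batch gradient descent
#' (Adam by default).  After every epoch the training loss and the full
#' validation metric set are recorded; training stops when validation
#' loss has not improved for `patience` epochs or at `max_epochs`, and
#' the weights from the best-validation-loss epoch are returned.
#' Training images can be augmented on the fly; validation images never
#' are.
#'
#' @param cfg an [arch_config()].
#' @param tcfg a [train_config()].
#' @param train_x,train_labels training batch array `(H, W, 3, N)` on
#'   `[0, 1]` and 0-based labels.
#' @param val_x,val_labels validation data, same conventions.
#' @param augment optional [augment_config()]; applied per epoch to the
#'   training images (with per-(epoch, image) seeds derived from
#'   `tcfg$seed`) before batching.
#' @param stop_on_val_accuracy optional threshold; training additionally
#'   stops as soon as validation accuracy reaches it (used by the
#'   desk-scale smoke checks to avoid burning the epoch budget after the
#'   target is met).
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights), `history` (per-epoch data
#'   frame), `best_epoch`.
#' @export
train_model <- function(cfg, tcfg, train_x, train_labels, val_x, val_labels,
                        augment = NULL, stop_on_val_accuracy = NULL,
                        verbose = FALSE) {
  if (!length(train_labels) || !length(val_labels)) stopf("empty train/val set")
  if (!all(sort(unique(val_labels)) %in% sort(unique(train_labels))))
    warnf("validation contains classes absent from training")
  set.seed(derive_seed(tcfg$seed, 101))
  model <- build_network(cfg)
  opt <- make_optimizer(tcfg$optimizer, tcfg$learning_rate, tcfg$weight_decay)
  n <- dim(train_x)[4]
  best <- list(loss = Inf, params = NULL, bn = NULL, epoch = 0L)
  wait <- 0L
  hist <- list()
  for (ep in seq_len(tcfg$max_epochs)) {
    x_ep <- train_x
    if (!is.null(augment)) {
      for (i in seq_len(n)) {
        set.seed(derive_seed(tcfg$seed, ep, i))
        im <- augment_pipeline(train_x[, , , i] * 255, augment)
        x_ep[, , , i] <- im / 255
      }
    }
    set.seed(derive_seed(tcfg$seed, 7, ep))
    ord <- sample.int(n)
    tr_loss <- 0
    for (s in seq(1, n, by = tcfg$batch_size)) {
      idx <- ord[s:min(s + tcfg$batch_size - 1, n)]
      xb <- x_ep[, , , idx, drop = FALSE]
      fwd <- network_forward_full(model, xb, training = TRUE)
      model <- fwd$model                       # updated running stats
      ce <- cross_entropy(fwd$logits, train_labels[idx] + 1L)
      if (!is.finite(ce$loss))
        stopf("training diverged at epoch %d (non-finite loss)", ep)
      tr_loss <- tr_loss + ce$loss * length(idx)
      bwd <- network_backward_full(model, fwd$caches, ce$grad)
      flat_g <- flatten_grads(model, bwd$grads)
      upd <- optimizer_step(opt, flatten_params(model), flat_g)
      opt <- upd$opt
      model <- set_params(model, upd$params)
    }
    ev <- eval_model(model, val_x, val_labels, tcfg$batch_size)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = tr_loss / n,
                             val_loss = ev$loss,
                             val_accuracy = ev$report$accuracy,
                             val_precision_macro = ev$report$precision_macro,
                             val_recall_macro = ev$report$recall_macro,
                             val_f1_macro = ev$report$f1_macro,
                             val_mcc = ev$report$mcc)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.4f",
                      ep, tr_loss / n, ev$loss, ev$report$accuracy))
    if (ev$loss < best$loss - 1e-9) {
      best <- list(loss = ev$loss, params = flatten_params(model),
                   bn = collect_bn_buffers(model), epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tcfg$patience) break
    }
    if (!is.null(stop_on_val_accuracy) &&
        ev$report$accuracy >= stop_on_val_accuracy) break
  }
  if (!is.null(best$params)) {
    model <- set_params(model, best$params)
    model <- restore_bn_buffers(model, best$bn)
  }
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold on the remaining folds (training-fold
#' augmentation only) and evaluates on the held-out fold.  Emits both
#' the best-epoch metrics per fold and the all-epoch history (the
#' distribution view), plus mean/sd summaries of fold accuracy and MCC.
#'
#' @param cfg,tcfg architecture and training configurations.
#' @param x,labels full dataset batch array and 0-based labels.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param augment optional [augment_config()] for training folds.
#' @param verbose passed to [train_model()].
#' @return list with `folds` (per-fold list of `report`, `history`,
#'   `best_epoch`), `summary` (data frame), `split`.
#' @export
cross_validate <- function(cfg, tcfg, x, labels, k = 5L, seed = 1L,
                           augment = NULL, verbose = FALSE) {
  split <- stratified_kfold(labels, k, seed)
  folds <- list()
  for (f in seq_len(k)) {
    tr <- which(split$assignments != f)
    va <- which(split$assignments == f)
    tf <- tcfg
    tf$seed <- derive_seed(tcfg$seed, 1000 + f)
    fit <- train_model(cfg, tf, x[, , , tr, drop = FALSE], labels[tr],
                       x[, , , va, drop = FALSE], labels[va],
                       augment = augment, verbose = verbose)
    ev <- eval_model(fit$model, x[, , , va, drop = FALSE], labels[va],
                     tcfg$batch_size)
    folds[[f]] <- list(report = ev$report, history = fit$history,
                       best_epoch = fit$best_epoch)
  }
  acc <- vapply(folds, function(f) f$report$accuracy, numeric(1))
  mccs <- vapply(folds, function(f) f$report$mcc, numeric(1))
  summary <- data.frame(metric = c("accuracy", "mcc"),
                        mean = c(mean(acc), mean(mccs)),
                        sd = c(stats::sd(acc), stats::sd(mccs)),
                        min = c(min(acc), min(mccs)),
                        max = c(max(acc), max(mccs)))
  list(folds = folds, summary = summary, split = split)
}

#' Combined random + grid hyperparameter search
#'
#' Evaluates every grid point plus uniform random draws from the ranges
#' until `budget` trials have run, ranks by the objective (higher is
#' better; conventionally mean validation accuracy) and returns the best
#' configuration with the full trial log.
#'
#' @param space list with optional `grid` (named list of value vectors)
#'   and `random` (named list of `c(low, high)` ranges; values drawn
#'   log-uniformly when `log = TRUE` attribute is set), and `budget`.
#' @param objective function(train_config) -> numeric score.
#' @param base a [train_config()] supplying unsearched fields.
#' @param seed RNG seed (search is reproducible given it).
#' @return list with `best` (train_config), `best_score`, `trials`
#'   (data frame).
#' @export
hyperparameter_search <- function(space, objective, base = train_config(),
                                  seed = 1L) {
  budget <- space$budget %||% 0L
  grid <- space$grid %||% list()
  rand <- space$random %||% list()
  if (!length(grid) && !length(rand)) stopf("empty search space")
  combos <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
            else data.frame()
  n_random <- max(0L, budget - nrow(combos))
  set.seed(seed)
  trials <- list()
  searched <- union(names(grid), names(rand))
  run_one <- function(vals) {
    tc <- base
    for (nm in names(vals)) tc[[nm]] <- vals[[nm]]
    score <- objective(tc)
    row <- lapply(searched, function(nm) tc[[nm]])
    names(row) <- searched
    c(row, list(score = score))
  }
  for (i in seq_len(nrow(combos)))
    trials[[length(trials) + 1L]] <- run_one(as.list(combos[i, , drop = FALSE]))
  for (i in seq_len(n_random)) {
    vals <- lapply(rand, function(rg) {
      if (isTRUE(attr(rg, "log"))) exp(runif(1, log(rg[1]), log(rg[2])))
      else runif(1, rg[1], rg[2])
    })
    trials[[length(trials) + 1L]] <- run_one(vals)
  }
  tl <- do.call(rbind, lapply(trials, function(t) as.data.frame(t)))
  best_i <- which.max(tl$score)
  best <- base
  for (nm in setdiff(names(tl), "score")) best[[nm]] <- tl[[nm]][best_i]
  list(best = best, best_score = tl$score[best_i], trials = tl)
}

#' Evaluate on an external test set with a leakage guard
#'
#' Refuses to run if any test path also appears among the training
#' paths; applies no augmentation; returns the full metrics report.
#'
#' @param model a trained model.
#' @param test_x,test_labels test batch array and labels.
#' @param test_paths,train_paths optional file-path vectors for the
#'   disjointness audit (error on overlap).
#' @param batch_size evaluation batch size.
#' @return a [metrics_report()].
#' @export
external_test <- function(model, test_x, test_labels, test_paths = NULL,
                          train_paths = NULL, batch_size = 32L) {
  if (!is.null(test_paths) && !is.null(train_paths)) {
    overlap <- intersect(normalizePath(test_paths, mustWork = FALSE),
                         normalizePath(train_paths, mustWork = FALSE))
    if (length(overlap))
      stopf("data leakage: %d test image(s) also present in training (e.g. '%s')",
            length(overlap), overlap[1])
  }
  eval_model(model, test_x, test_labels, batch_size)$report
}
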