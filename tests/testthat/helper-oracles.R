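# Independent reference implementations used as oracles.  These are
# deliberately written on different computational routes than the
# package (per-sample loops, one-hot covariances, pairwise AUC counts)
# so agreement is informative.

o_accuracy <- function(true, pred) mean(true == pred)

o_precision_class <- function(true, pred, k) {
  denom <- sum(pred == k)
  if (denom == 0) 0 else sum(true == k & pred == k) / denom
}

o_recall_class <- function(true, pred, k) {
  denom <- sum(true == k)
  if (denom == 0) 0 else sum(true == k & pred == k) / denom
}

o_micro <- function(true, pred, K) {
  tp <- sum(true == pred)
  fp <- sum(true != pred)   # every wrong prediction is an FP for some class
  fn <- sum(true != pred)
  c(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

o_macro <- function(true, pred, K) {
  cls <- 0:(K - 1)
  c(precision = mean(sapply(cls, function(k) o_precision_class(true, pred, k))),
    recall = mean(sapply(cls, function(k) o_recall_class(true, pred, k))))
}

# Multiclass MCC as a Pearson correlation over one-hot sample indicators
# (a different route than the confusion-matrix covariance form).
o_mcc <- function(true, pred, K) {
  n <- length(true)
  X <- sapply(0:(K - 1), function(k) as.numeric(pred == k))
  Y <- sapply(0:(K - 1), function(k) as.numeric(true == k))
  cx <- scale(X, scale = FALSE); cy <- scale(Y, scale = FALSE)
  num <- sum(cx * cy)
  den <- sqrt(sum(cx * cx)) * sqrt(sum(cy * cy))
  if (den == 0) 0 else num / den
}

# ROC AUC by Mann-Whitney pair counting (ties counted half).
o_roc_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Average precision over the ranked list (distinct scores assumed).
o_pr_auc <- function(y, s) {
  o <- order(s, decreasing = TRUE)
  y <- y[o]
  P <- sum(y)
  if (P == 0) return(NA_real_)
  prec_at <- cumsum(y) / seq_along(y)
  sum(prec_at[y == 1]) / P
}

rand_triple <- function(n = 60, K = 3) {
  true <- sample(0:(K - 1), n, replace = TRUE)
  pred <- ifelse(runif(n) < 0.6, true, sample(0:(K - 1), n, replace = TRUE))
  raw <- matrix(runif(n * K), n, K) + 0.5 * sapply(0:(K - 1), function(k) true == k)
  scores <- raw / rowSums(raw)
  list(true = true, pred = pred, scores = scores)
}
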