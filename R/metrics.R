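# Multi-class evaluation: confusion matrix, accuracy, micro/macro
# precision and recall, F1, Matthews correlation (binary formula and the
# multiclass covariance generalisation), plus report assembly.
#
# Zero-denominator convention throughout: the affected term is 0 and a
# warning is raised (this matters on tiny folds; documented because it
# feeds macro averages).

#' Confusion matrix from label vectors
#'
#' @param true,pred integer class labels in `0:(K-1)` (or factors/values
#'   coercible to them), equal length.
#' @param K number of classes.
#' @param class_names optional K labels.
#' @return a `confusion_matrix`: K x K integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(true, pred, K, class_names = NULL) {
  true <- as.integer(true); pred <- as.integer(pred)
  if (length(true) != length(pred)) stopf("label vectors differ in length")
  if (any(true < 0 | true >= K) || any(pred < 0 | pred >= K))
    stopf("labels must lie in [0, %d)", K)
  cm <- matrix(0L, K, K)
  for (i in seq_along(true))
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  if (is.null(class_names)) class_names <- as.character(seq_len(K) - 1L)
  dimnames(cm) <- list(true = class_names, predicted = class_names)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

cm_counts <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- sum(cm) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn, total = sum(cm))
}

#' Overall accuracy: trace / total
#' @param cm a [confusion()] matrix.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  if (sum(cm) == 0) stopf("accuracy undefined on an empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warnf("%s has zero denominator; defined as 0", what)
    return(0)
  }
  num / den
}

#' Micro-averaged precision and recall
#'
#' Aggregates true/false positives and false negatives across classes
#' before forming the ratios.  For single-label multiclass data micro
#' precision, micro recall and accuracy coincide.
#'
#' @param cm a [confusion()] matrix.
#' @return named vector `c(precision, recall)`.
#' @export
precision_recall_micro <- function(cm) {
  k <- cm_counts(cm)
  c(precision = safe_div(sum(k$tp), sum(k$tp) + sum(k$fp), "micro precision"),
    recall = safe_div(sum(k$tp), sum(k$tp) + sum(k$fn), "micro recall"))
}

#' Macro-averaged precision and recall
#'
#' Per-class ratios averaged with equal class weight; a class with no
#' predicted (resp. actual) positives contributes 0 to its term.
#'
#' @param cm a [confusion()] matrix.
#' @return named vector `c(precision, recall)`.
#' @export
precision_recall_macro <- function(cm) {
  k <- cm_counts(cm)
  prec <- ifelse(k$tp + k$fp == 0, 0, k$tp / (k$tp + k$fp))
  rec <- ifelse(k$tp + k$fn == 0, 0, k$tp / (k$tp + k$fn))
  if (any(k$tp + k$fp == 0)) warnf("a class was never predicted; its precision term is 0")
  if (any(k$tp + k$fn == 0)) warnf("a class has no true samples; its recall term is 0")
  c(precision = mean(prec), recall = mean(rec))
}

#' F1 score: harmonic mean of precision and recall
#' @param precision,recall values in `[0, 1]`.
#' @return F1 in `[0, 1]`; 0 when both inputs are 0.
#' @export
f1 <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Matthews correlation coefficient
#'
#' For two classes this is the familiar
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; for more
#' classes the covariance-form multiclass generalisation
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2))(s^2 - sum(t_k^2)))`
#' with `c` the trace, `s` the total, `p_k`/`t_k` the predicted/true
#' column and row sums.  The two agree at K = 2.  Undefined denominators
#' give 0.
#'
#' @param cm a [confusion()] matrix.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  s <- sum(cm)
  if (s == 0) return(0)
  tr <- sum(diag(cm))
  p <- colSums(cm)   # predicted per class
  t <- rowSums(cm)   # true per class
  num <- tr * s - sum(p * t)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) return(0)
  num / den
}

#' Per-class one-vs-rest binary MCCs (and their mean)
#'
#' Provided alongside the covariance form because published single-value
#' summaries of multiclass MCC are sometimes one-vs-rest averages.
#'
#' @param cm a [confusion()] matrix.
#' @return list with `per_class` vector and `mean`.
#' @export
mcc_one_vs_rest <- function(cm) {
  k <- cm_counts(cm)
  per <- mapply(function(tp, fp, fn, tn) {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }, k$tp, k$fp, k$fn, k$tn)
  list(per_class = per, mean = mean(per))
}

#' Assemble the full metrics report
#'
#' @param true integer labels in `0:(K-1)`.
#' @param pred predicted labels, same coding.
#' @param scores optional N x K matrix of class scores (rows sum to 1);
#'   enables the ROC / precision-recall block.
#' @param K number of classes.
#' @param class_names optional labels.
#' @return a `metrics_report` list: `confusion`, `accuracy`,
#'   `precision_micro`, `recall_micro`, `precision_macro`, `recall_macro`,
#'   `f1_micro`, `f1_macro`, `mcc`, `mcc_ovr`, `per_class` (data frame),
#'   and `curves` when scores are given.
#' @export
metrics_report <- function(true, pred, scores = NULL, K = max(true, pred) + 1L,
                           class_names = NULL) {
  cm <- confusion(true, pred, K, class_names)
  mic <- suppressWarnings(precision_recall_micro(cm))
  mac <- suppressWarnings(precision_recall_macro(cm))
  k <- cm_counts(cm)
  per <- data.frame(
    class = rownames(cm),
    precision = ifelse(k$tp + k$fp == 0, 0, k$tp / (k$tp + k$fp)),
    recall = ifelse(k$tp + k$fn == 0, 0, k$tp / (k$tp + k$fn)))
  per$f1 <- mapply(f1, per$precision, per$recall)
  rep <- list(confusion = cm, accuracy = accuracy(cm),
              precision_micro = unname(mic["precision"]),
              recall_micro = unname(mic["recall"]),
              precision_macro = unname(mac["precision"]),
              recall_macro = unname(mac["recall"]),
              f1_micro = f1(mic["precision"], mic["recall"]),
              f1_macro = f1(mac["precision"], mac["recall"]),
              mcc = mcc(cm), mcc_ovr = mcc_one_vs_rest(cm),
              per_class = per)
  if (!is.null(scores)) {
    cur <- roc_pr_curves(list(true_labels = true, scores = scores))
    rep$curves <- cur
    rep$per_class$roc_auc <- cur$per_class$roc_auc[match(per$class, cur$per_class$class)]
    rep$per_class$pr_auc <- cur$per_class$pr_auc[match(per$class, cur$per_class$class)]
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d acc=%.4f macroP=%.4f macroR=%.4f mcc=%.4f\n",
              sum(x$confusion), x$accuracy, x$precision_macro,
              x$recall_macro, x$mcc))
  invisible(x)
}

#' Serialise a metrics report
#'
#' Writes `<prefix>_metrics.json`, `<prefix>_confusion.csv` and, when
#' curves are present, `<prefix>_curves.csv` (columns: class, curve,
#' threshold, x, y) for replotting.
#'
#' @param rep a [metrics_report()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_metrics_report <- function(rep, prefix) {
  paths <- character()
  scal <- rep[c("accuracy", "precision_micro", "recall_micro",
                "precision_macro", "recall_macro", "f1_micro", "f1_macro",
                "mcc")]
  scal$mcc_ovr_mean <- rep$mcc_ovr$mean
  scal$per_class <- rep$per_class
  if (!is.null(rep$curves)) {
    scal$roc_auc_micro <- rep$curves$micro$roc_auc
    scal$roc_auc_macro <- rep$curves$macro$roc_auc
    scal$pr_auc_micro <- rep$curves$micro$pr_auc
    scal$pr_auc_macro <- rep$curves$macro$pr_auc
  }
  jp <- paste0(prefix, "_metrics.json")
  jsonlite::write_json(scal, jp, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, jp)
  cp <- paste0(prefix, "_confusion.csv")
  utils::write.csv(as.data.frame(unclass(rep$confusion)), cp)
  paths <- c(paths, cp)
  if (!is.null(rep$curves)) {
    vp <- paste0(prefix, "_curves.csv")
    utils::write.csv(rep$curves$points, vp, row.names = FALSE)
    paths <- c(paths, vp)
  }
  invisible(paths)
}
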