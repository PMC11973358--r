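# One-vs-rest ROC and precision-recall curves with micro/macro averaging.
#
# ROC AUC is the trapezoidal area over the threshold sweep; PR AUC uses
# the step-wise sum (no linear interpolation of precision), the standard
# for imbalanced data.

# Binary curves for one score vector; y is 0/1.
binary_curves <- function(y, s) {
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  # collapse ties: cumulative counts at each distinct threshold
  tps <- cumsum(y)
  fps <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tps <- tps[keep]; fps <- fps[keep]; thr <- s[keep]
  P <- sum(y); Ng <- length(y) - P
  tpr <- c(0, tps / P)
  fpr <- c(0, if (Ng > 0) fps / Ng else fps * 0)
  roc_auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  prec <- tps / (tps + fps)
  rec <- tps / P
  pr_auc <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(threshold = c(Inf, thr), x = fpr, y = tpr),
       pr = data.frame(threshold = thr, x = rec, y = prec),
       roc_auc = roc_auc, pr_auc = pr_auc)
}

#' One-vs-rest ROC and precision-recall curves with AUCs
#'
#' Each class is binarised against the rest; per-class curves and AUCs
#' are computed, the micro average pools every (sample, class) decision
#' into one binary problem, and the macro average is the unweighted mean
#' of per-class AUCs.  A class with no positive samples is skipped with a
#' warning and excluded from the macro mean.
#'
#' @param scoreset list with `true_labels` (integer labels in `0:(K-1)`)
#'   and `scores` (N x K matrix; rows should sum to 1).
#' @return list with `per_class` (data frame of AUCs), `micro`, `macro`,
#'   and `points` (long data frame of all curve points: class, curve,
#'   threshold, x, y).
#' @export
roc_pr_curves <- function(scoreset) {
  true <- as.integer(scoreset$true_labels)
  scores <- as.matrix(scoreset$scores)
  K <- ncol(scores)
  n <- length(true)
  if (nrow(scores) != n) stopf("scores and labels disagree in length")
  pts <- list(); per <- list()
  roc_aucs <- c(); pr_aucs <- c()
  for (k in seq_len(K)) {
    y <- as.integer(true == (k - 1L))
    if (sum(y) == 0 || sum(y) == n) {
      warnf("class %d has no %s samples; curve skipped", k - 1L,
            if (sum(y) == 0) "positive" else "negative")
      per[[k]] <- data.frame(class = as.character(k - 1L), roc_auc = NA_real_,
                             pr_auc = NA_real_)
      next
    }
    b <- binary_curves(y, scores[, k])
    roc_aucs <- c(roc_aucs, b$roc_auc); pr_aucs <- c(pr_aucs, b$pr_auc)
    per[[k]] <- data.frame(class = as.character(k - 1L),
                           roc_auc = b$roc_auc, pr_auc = b$pr_auc)
    pts[[length(pts) + 1L]] <- cbind(class = as.character(k - 1L), curve = "roc", b$roc)
    pts[[length(pts) + 1L]] <- cbind(class = as.character(k - 1L), curve = "pr", b$pr)
  }
  yy <- as.integer(as.vector(outer(true, 0:(K - 1L), "==")))
  mb <- binary_curves(yy, as.vector(scores))
  pts[[length(pts) + 1L]] <- cbind(class = "micro", curve = "roc", mb$roc)
  pts[[length(pts) + 1L]] <- cbind(class = "micro", curve = "pr", mb$pr)
  list(per_class = do.call(rbind, per),
       micro = list(roc_auc = mb$roc_auc, pr_auc = mb$pr_auc),
       macro = list(roc_auc = mean(roc_aucs), pr_auc = mean(pr_aucs)),
       points = do.call(rbind, pts))
}
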