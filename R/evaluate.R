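# Evaluation: confusion matrix, per-class/overall accuracy, and
# micro-averaged ROC/AUC for multiclass probabilistic classifiers.

#' Confusion matrix and accuracies
#'
#' @param y_true,y_pred 0-based integer label vectors of equal length.
#' @param n_classes number of classes `C`.
#' @return list with `confusion` (`C x C`, rows = true class), `per_class`
#'   accuracy (diagonal over row sums) and `overall` accuracy (trace over n).
#' @export
confusion_and_accuracy <- function(y_true, y_pred, n_classes = max(y_true, y_pred) + 1L) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1), pred = 0:(n_classes - 1)))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  rs <- rowSums(cm)
  list(confusion = cm,
       per_class = ifelse(rs > 0, diag(cm) / rs, NA_real_),
       overall = sum(diag(cm)) / length(y_true))
}

#' Micro-averaged multiclass ROC curve and AUC
#'
#' Flattens the `m x n` 0/1 label matrix `L` and probability matrix `P` into
#' two vectors of length `m * n`, turning the multiclass problem into one
#' binary problem, then sweeps a threshold over the flattened scores: at each
#' distinct score, `TPR = TP / (TP + FN)` and `FPR = FP / (TN + FP)`. The
#' AUC is the trapezoidal integral of TPR over FPR. Tied scores form a
#' single operating point.
#'
#' @param L 0/1 label matrix (`m` samples x `n` classes), or a 0-based label
#'   vector which is one-hot encoded against `ncol(P)`.
#' @param P probability/score matrix of the same shape.
#' @return list with `fpr`, `tpr`, `thresholds` and `auc`.
#' @export
micro_roc <- function(L, P) {
  P <- as.matrix(P)
  if (!is.matrix(L)) L <- one_hot(L, ncol(P))
  if (!identical(dim(L), dim(P))) stop_shape("micro_roc", dim(L), dim(P))
  scores <- as.vector(P)
  labels <- as.vector(L)
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  # one operating point per distinct threshold
  last <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- cumsum(labels)[last]
  fp <- cumsum(1 - labels)[last]
  npos <- sum(labels); nneg <- length(labels) - npos
  tpr <- c(0, tp / npos)
  fpr <- c(0, fp / nneg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, scores[last]), auc = auc)
}

#' Full evaluation report for a probabilistic classifier
#'
#' @param y_true 0-based labels.
#' @param proba `n x C` probability matrix.
#' @return list combining [confusion_and_accuracy()] and [micro_roc()]
#'   results.
#' @export
evaluate_classifier <- function(y_true, proba) {
  pred <- max.col(proba) - 1L
  acc <- confusion_and_accuracy(y_true, pred, ncol(proba))
  roc <- micro_roc(one_hot(y_true, ncol(proba)), proba)
  c(acc, list(micro_roc = roc[c("fpr", "tpr")], micro_auc = roc$auc))
}
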