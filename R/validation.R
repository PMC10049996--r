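#' ROC curve and AUC for a scored cohort
#'
#' Sweeps the decision threshold over the unique score values in
#' descending order (ties grouped, one point per unique score), predicting
#' positive at score >= threshold, and records the (false-positive rate,
#' true-positive rate) path from (0, 0) to (1, 1). The AUC is the
#' trapezoidal area under that path, which equals the Mann-Whitney
#' concordance probability with ties counted one half.
#'
#' Implemented directly (counting sort over unique scores) so it can be
#' cross-checked against independent oracles.
#'
#' @param scores Numeric risk scores; any strictly increasing transform
#'   (logit, probability, LP) yields the same curve.
#' @param labels Binary outcome labels (1/0 or TRUE/FALSE), same length;
#'   both classes must be present.
#' @return An object of class `roc_summary`: list with `points`
#'   (data.frame `threshold`, `fpr`, `tpr`, beginning at (0,0) with
#'   threshold `Inf`), `auc`, and the input `n_pos` / `n_neg`.
#' @export
#' @examples
#' roc <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' roc$auc
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: both classes must be present in labels")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # group ties: cumulative counts at the last index of each unique score
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  points <- data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("ROC: %d cases vs %d controls, %d threshold points, AUC %.4f\n",
              x$n_pos, x$n_neg, nrow(x$points), x$auc))
  if (!is.null(x$operating_point)) {
    op <- x$operating_point
    cat(sprintf("operating point (score >= %g): sensitivity %.3f, specificity %.3f\n",
                op$threshold, op$sensitivity, op$specificity))
  }
  invisible(x)
}

#' Confusion matrix and rates at a fixed threshold
#'
#' Predicts positive at score >= threshold (ties positive) and reports the
#' confusion counts together with sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP) and accuracy.
#'
#' @inheritParams roc_curve
#' @param threshold Decision threshold on the score scale.
#' @return list with `threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
#' @examples
#' evaluate_at(c(3, 2.5, 1, 0.5), c(1, 1, 0, 0), threshold = 2.24)
evaluate_at <- function(scores, labels, threshold) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  stopifnot(length(scores) == length(labels), length(threshold) == 1L)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(labels))
}

#' Youden-optimal operating point of an ROC curve
#'
#' The threshold maximising sensitivity + specificity - 1 (Youden's J).
#' Ties broken toward the higher threshold (more specific).
#'
#' @param roc A `roc_summary` from [roc_curve()].
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_point <- function(roc) {
  stopifnot(inherits(roc, "roc_summary"))
  pts <- roc$points
  j <- pts$tpr - pts$fpr
  best <- which.max(j)  # which.max takes the first (highest threshold) tie
  list(threshold = pts$threshold[best], sensitivity = pts$tpr[best],
       specificity = 1 - pts$fpr[best], youden_j = j[best])
}

#' Full validation summary of a scored cohort
#'
#' ROC curve and AUC, plus confusion metrics at a requested operating
#' threshold (default: the published LP cut-off 2.24 when scores are LP
#' values) and at the Youden-optimal point, clearly labelled.
#'
#' @inheritParams roc_curve
#' @param threshold Operating threshold; `NULL` to skip.
#' @return `roc_summary` with added `operating_point` and `youden` fields.
#' @export
validate_scores <- function(scores, labels, threshold = 2.24) {
  roc <- roc_curve(scores, labels)
  if (!is.null(threshold)) {
    roc$operating_point <- evaluate_at(scores, labels, threshold)
  }
  roc$youden <- youden_point(roc)
  roc
}

#' Export ROC points as CSV
#'
#' Columns `fpr,tpr,threshold`, one row per swept threshold.
#'
#' @param roc A `roc_summary`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_summary"))
  utils::write.csv(roc$points[, c("fpr", "tpr", "threshold")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
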