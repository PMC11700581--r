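## Evaluation metrics: accuracy, macro precision/recall/F1, macro MCC,
## micro/macro AUROC and micro AUPRC, all computed one-vs-rest from a
## samples x classes score matrix. AUROC uses the rank (Mann-Whitney)
## statistic: tied pairs earn half credit. AUPRC uses the step-wise
## (non-interpolated) precision-recall area with ties grouped by threshold.

#' One-vs-rest confusion counts
#'
#' @param yTrue,yPred Integer class indices (1-based) or factors over the
#'   same levels.
#' @param nClasses Number of classes.
#' @return Matrix nClasses x 4 with columns TP, FP, FN, TN.
#' @export
confusionCounts <- function(yTrue, yPred, nClasses) {
  yTrue <- as.integer(yTrue)
  yPred <- as.integer(yPred)
  .assert(length(yTrue) > 0L, "empty input")
  .assert(length(yTrue) == length(yPred), "length mismatch")
  .assert(all(yTrue >= 1 & yTrue <= nClasses) &&
            all(yPred >= 1 & yPred <= nClasses), "labels out of range")
  n <- length(yTrue)
  out <- matrix(0L, nClasses, 4L,
                dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  for (i in seq_len(nClasses)) {
    tp <- sum(yTrue == i & yPred == i)
    fp <- sum(yTrue != i & yPred == i)
    fn <- sum(yTrue == i & yPred != i)
    out[i, ] <- c(tp, fp, fn, n - tp - fp - fn)
  }
  out
}

.safeDiv <- function(num, den) ifelse(den == 0, 0, num / den)

#' Macro-averaged precision, recall and F1
#'
#' Unweighted means over classes; a class with an undefined ratio (zero
#' denominator) contributes 0.
#'
#' @param counts Confusion count matrix from \code{\link{confusionCounts}}.
#' @return \code{macroF1}: scalar. \code{macroPrecisionRecall}: list with
#'   \code{precision}, \code{recall} and the per-class vectors.
#' @export
macroF1 <- function(counts) {
  pr <- .safeDiv(counts[, "TP"], counts[, "TP"] + counts[, "FP"])
  rc <- .safeDiv(counts[, "TP"], counts[, "TP"] + counts[, "FN"])
  f1 <- .safeDiv(2 * pr * rc, pr + rc)
  mean(f1)
}

#' @rdname macroF1
#' @export
macroPrecisionRecall <- function(counts) {
  pr <- .safeDiv(counts[, "TP"], counts[, "TP"] + counts[, "FP"])
  rc <- .safeDiv(counts[, "TP"], counts[, "TP"] + counts[, "FN"])
  list(precision = mean(pr), recall = mean(rc),
       perClassPrecision = pr, perClassRecall = rc)
}

#' Macro-averaged Matthews correlation coefficient
#'
#' Per-class binary MCC (one-vs-rest), with 0 substituted when any
#' denominator factor vanishes, averaged over classes.
#'
#' @param counts Confusion count matrix.
#' @return Scalar in [-1, 1].
#' @export
macroMCC <- function(counts) {
  tp <- as.numeric(counts[, "TP"]); fp <- as.numeric(counts[, "FP"])
  fn <- as.numeric(counts[, "FN"]); tn <- as.numeric(counts[, "TN"])
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(den == 0, 0, (tp * tn - fp * fn) / den)
  mean(mcc)
}

## Binary AUROC by average ranks; half credit for tied pairs.
.binaryAUROC <- function(scores, pos) {
  np <- sum(pos)
  nn <- sum(!pos)
  .assert(np > 0 && nn > 0, "AUROC needs both positives and negatives")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

## Binary step-wise AUPRC: thresholds at distinct scores, descending;
## area = sum (R_k - R_{k-1}) * P_k.
.binaryAUPRC <- function(scores, pos) {
  np <- sum(pos)
  .assert(np > 0, "AUPRC needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- pos[o]
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(y)
  allCum <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tpCum[last]
  npred <- allCum[last]
  prec <- tp / npred
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Micro- and macro-averaged AUROC and micro AUPRC
#'
#' Micro variants flatten all one-vs-rest (sample, class) pairs into one
#' binary problem; macro AUROC averages per-class AUROCs (classes without
#' positives or without negatives are skipped).
#'
#' @param scores Samples x classes score matrix.
#' @param yTrue Integer class indices (1-based), factor, or a binary
#'   samples x classes matrix (multi-label).
#' @return Scalar in [0, 1].
#' @export
microAUC <- function(scores, yTrue) {
  Y <- .asIndicator(yTrue, ncol(scores))
  .binaryAUROC(as.vector(scores), as.vector(Y) == 1)
}

#' @rdname microAUC
#' @export
macroAUC <- function(scores, yTrue) {
  Y <- .asIndicator(yTrue, ncol(scores))
  aucs <- vapply(seq_len(ncol(scores)), function(i) {
    pos <- Y[, i] == 1
    if (all(pos) || !any(pos)) return(NA_real_)
    .binaryAUROC(scores[, i], pos)
  }, 0)
  mean(aucs, na.rm = TRUE)
}

#' @rdname microAUC
#' @export
microAUPRC <- function(scores, yTrue) {
  Y <- .asIndicator(yTrue, ncol(scores))
  .binaryAUPRC(as.vector(scores), as.vector(Y) == 1)
}

.asIndicator <- function(yTrue, nClasses) {
  if (is.matrix(yTrue)) {
    .assert(ncol(yTrue) == nClasses, "indicator matrix has wrong width")
    return(yTrue)
  }
  y <- as.integer(yTrue)
  Y <- matrix(0L, length(y), nClasses)
  Y[cbind(seq_along(y), y)] <- 1L
  Y
}

#' Full metrics panel
#'
#' Computes accuracy, macro precision/recall/F1, macro MCC, micro and macro
#' AUROC, micro AUPRC and the per-class confusion counts from a score
#' matrix (predictions are argmax over columns).
#'
#' @param scores Samples x classes score matrix.
#' @param yTrue Integer indices (1-based) or factor over the class levels.
#' @param classNames Optional class names for the report.
#' @return A list of class \code{"MetricsReport"}.
#' @export
computeMetrics <- function(scores, yTrue, classNames = colnames(scores)) {
  y <- as.integer(yTrue)
  .assert(length(y) == nrow(scores), "yTrue must match rows of scores")
  yPred <- max.col(scores, ties.method = "first")
  counts <- confusionCounts(y, yPred, ncol(scores))
  if (!is.null(classNames)) rownames(counts) <- classNames
  mpr <- macroPrecisionRecall(counts)
  rep <- list(acc = mean(yPred == y),
              macro_precision = mpr$precision,
              macro_recall = mpr$recall,
              macro_f1 = macroF1(counts),
              macro_mcc = macroMCC(counts),
              mi_auc = microAUC(scores, y),
              ma_auc = macroAUC(scores, y),
              mi_auprc = microAUPRC(scores, y),
              counts = counts)
  class(rep) <- "MetricsReport"
  rep
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "ACC %.4f | maP %.4f | maR %.4f | maF1 %.4f | MCC %.4f\n",
    x$acc, x$macro_precision, x$macro_recall, x$macro_f1, x$macro_mcc))
  cat(sprintf("miAUC %.4f | maAUC %.4f | miAUPRC %.4f\n",
              x$mi_auc, x$ma_auc, x$mi_auprc))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report A \code{MetricsReport}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsJSON <- function(report, path) {
  out <- report[setdiff(names(report), "counts")]
  out$counts <- as.data.frame(report$counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
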