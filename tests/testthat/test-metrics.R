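# Evaluation metrics: hand-counted confusion examples, worked macro F1 /
# MCC values, AUROC/AUPRC edge cases, and brute-force oracle equivalence.

## pair-counting AUROC oracle (half credit for ties)
bruteAUROC <- function(scores, pos) {
  ps <- scores[pos]
  ns <- scores[!pos]
  tot <- 0
  for (a in ps) for (b in ns)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

## naive threshold-sweep AUPRC oracle (step-wise, right-continuous)
bruteAUPRC <- function(scores, pos) {
  np <- sum(pos)
  th <- sort(unique(scores), decreasing = TRUE)
  prevR <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(pos & sel) / sum(sel)
    rec <- sum(pos & sel) / np
    area <- area + (rec - prevR) * prec
    prevR <- rec
  }
  area
}

test_that("confusion counts match the hand-worked example", {
  cc <- confusionCounts(c(1, 1, 2, 2), c(1, 2, 2, 2), 2L)
  expect_equal(unname(cc[1L, ]), c(1L, 0L, 1L, 2L))  # TP FP FN TN
  expect_equal(unname(cc[2L, ]), c(2L, 1L, 0L, 1L))
  ## perfect predictions: no FP/FN anywhere
  cp <- confusionCounts(1:3, 1:3, 3L)
  expect_true(all(cp[, c("FP", "FN")] == 0))
  ## single observed class: others have zero TP
  cs <- confusionCounts(c(1, 1), c(1, 1), 3L)
  expect_equal(unname(cs[2:3, "TP"]), c(0L, 0L))
  expect_error(confusionCounts(integer(), integer(), 2L), "empty")
})

test_that("macro F1 matches per-class arithmetic", {
  cc <- confusionCounts(c(1, 1, 2, 2), c(1, 2, 2, 2), 2L)
  # class 1: P=1, R=0.5 -> F1 2/3; class 2: P=2/3, R=1 -> F1 0.8
  expect_equal(macroF1(cc), (2 / 3 + 0.8) / 2, tolerance = 1e-12)
  expect_equal(macroF1(cc), 0.7333, tolerance = 1e-4)
  expect_equal(macroF1(confusionCounts(1:3, 1:3, 3L)), 1)
  ## all wrong on a balanced 2-class set
  expect_equal(macroF1(confusionCounts(c(1, 2), c(2, 1), 2L)), 0)
})

test_that("macro MCC covers the worked and degenerate cases", {
  # TP=TN=FP=FN=1 per class: numerator 0
  cc <- matrix(1L, 2, 4, dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  expect_equal(macroMCC(cc), 0)
  expect_equal(macroMCC(confusionCounts(c(1, 1, 2, 2), c(1, 1, 2, 2), 2L)), 1)
  expect_equal(macroMCC(confusionCounts(c(1, 1, 2, 2), c(2, 2, 1, 1), 2L)), -1)
  ## zero denominator -> 0 contribution
  cz <- confusionCounts(c(1, 1), c(1, 1), 2L)
  expect_true(is.finite(macroMCC(cz)))
})

test_that("binary AUROC reproduces the worked 0.75 example and edge cases", {
  s <- cbind(1 - c(0.9, 0.8, 0.4, 0.3), c(0.9, 0.8, 0.4, 0.3))
  y <- c(2L, 1L, 2L, 1L)  # labels 1 0 1 0 for class 2
  expect_equal(macroAUC(s, y), 0.75)
  ## perfectly separated
  sep <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(macroAUC(sep, c(1L, 1L, 2L, 2L)), 1)
  expect_equal(microAUPRC(sep, c(1L, 1L, 2L, 2L)), 1)
  ## ties everywhere -> chance
  tie <- matrix(0.5, 4, 2)
  expect_equal(macroAUC(tie, c(1L, 2L, 1L, 2L)), 0.5)
})

test_that("accuracy equals the mean of per-sample correctness exactly", {
  set.seed(25)
  s <- matrix(runif(60), 20, 3)
  y <- sample(3L, 20L, replace = TRUE)
  rep <- computeMetrics(s, y)
  expect_identical(rep$acc, mean(max.col(s, "first") == y))
})

test_that("all metrics match brute-force oracles on 50 random instances", {
  set.seed(26)
  worst <- 0
  for (i in 1:50) {
    m <- sample(6:20, 1)
    n <- sample(2:4, 1)
    s <- matrix(round(runif(m * n), 2), m, n)  # rounding forces ties
    y <- sample(n, m, replace = TRUE)
    while (length(unique(y)) < 2L) y <- sample(n, m, replace = TRUE)
    Y <- matrix(0L, m, n)
    Y[cbind(1:m, y)] <- 1L

    worst <- max(worst,
      abs(microAUC(s, y) - bruteAUROC(as.vector(s), as.vector(Y) == 1)),
      abs(microAUPRC(s, y) - bruteAUPRC(as.vector(s), as.vector(Y) == 1)))
    percls <- vapply(seq_len(n), function(k) {
      if (!any(y == k)) return(NA_real_)
      bruteAUROC(s[, k], y == k)
    }, 0)
    worst <- max(worst, abs(macroAUC(s, y) - mean(percls, na.rm = TRUE)))
    ## macro F1 / MCC against direct per-class recomputation
    pred <- max.col(s, "first")
    f1 <- mcc <- numeric(n)
    for (k in seq_len(n)) {
      tp <- sum(y == k & pred == k); fp <- sum(y != k & pred == k)
      fn <- sum(y == k & pred != k); tn <- m - tp - fp - fn
      pr <- if (tp + fp > 0) tp / (tp + fp) else 0
      rc <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1[k] <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
      den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
      mcc[k] <- if (den > 0) (tp * tn - fp * fn) / den else 0
    }
    cnt <- confusionCounts(y, pred, n)
    worst <- max(worst, abs(macroF1(cnt) - mean(f1)),
                 abs(macroMCC(cnt) - mean(mcc)))
  }
  expect_lt(worst, 1e-9)
})

test_that("computeMetrics assembles a complete, in-range report", {
  set.seed(27)
  s <- matrix(runif(45), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
  s <- s / rowSums(s)
  y <- sample(3L, 15L, replace = TRUE)
  rep <- computeMetrics(s, y)
  expect_s3_class(rep, "MetricsReport")
  for (nm in c("acc", "macro_precision", "macro_recall", "macro_f1",
               "mi_auc", "ma_auc", "mi_auprc"))
    expect_true(rep[[nm]] >= 0 && rep[[nm]] <= 1)
  expect_true(rep$macro_mcc >= -1 && rep$macro_mcc <= 1)
  expect_equal(rownames(rep$counts), c("a", "b", "c"))
  ## counts consistency: TP + FN equals the class support
  expect_equal(unname(rep$counts[, "TP"] + rep$counts[, "FN"]),
               as.integer(table(factor(y, levels = 1:3))))
  ## JSON serialization round-trips the scalar metrics
  f <- withr::local_tempfile(fileext = ".json")
  writeMetricsJSON(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$macro_f1, rep$macro_f1, tolerance = 1e-12)
})
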