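## Training: stratified k-fold assignment, the AdamW optimization loop with
## early stopping on validation macro F1, cross-validation, and grid search.

#' Stratified k-fold assignment
#'
#' Deterministic given the seed. Members of each class are shuffled and
#' dealt greedily to the currently smallest folds, so per-class counts per
#' fold differ by at most one and total fold sizes differ by at most one.
#'
#' @param labels Factor (single-label) or binary matrix (multi-label, in
#'   which case stratification is on the label combination).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @param warnSmall Warn about classes with fewer than \code{k} members?
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratifiedFolds <- function(labels, k = 5L, seed = 1L, warnSmall = TRUE) {
  if (is.matrix(labels)) {
    strata <- factor(apply(labels, 1L, paste, collapse = ""))
  } else strata <- factor(labels)
  n <- length(strata)
  .assert(k >= 2L && k <= n, "k must be between 2 and the sample count")
  small <- names(which(table(strata) < k))
  if (warnSmall && length(small))
    warning(sprintf("classes with fewer than %d members: %s", k,
                    paste(small, collapse = ", ")))
  withSeed(seed, {
    fold <- integer(n)
    total <- integer(k)
    for (cl in levels(strata)) {
      idx <- which(strata == cl)
      idx <- idx[sample.int(length(idx))]
      ## deal this class round-robin over folds ordered by current size
      ## (ties by fold index): per-class counts per fold differ by <= 1,
      ## and total fold sizes stay within 1 of each other by induction
      ord <- order(total, seq_len(k))
      dealt <- ord[(seq_along(idx) - 1L) %% k + 1L]
      fold[idx] <- dealt
      total <- total + tabulate(dealt, k)
    }
    fold
  })
}

.datasetTargets <- function(dataset) {
  if (labelMode(dataset) == "single") as.integer(labels(dataset))
  else labels(dataset)
}

## One optimization epoch over pre-encoded inputs; returns mean batch loss.
.runEpoch <- function(encsT, target, params, state, cfg, mode) {
  n <- length(encsT)
  perm <- sample.int(n)
  bs <- cfg$train$batch_size
  lossSum <- 0
  nb <- 0L
  for (s in seq(1L, n, by = bs)) {
    idx <- perm[s:min(s + bs - 1L, n)]
    fw <- .modelForwardBatch(encsT[idx], params, cfg, mode, training = TRUE)
    lg <- if (mode == "single") {
      .focalMulticlassGrad(fw$probs, target[idx], cfg$loss$alpha,
                           cfg$loss$gamma, cfg$loss$eps)
    } else {
      .focalMultilabelGrad(fw$probs, target[idx, , drop = FALSE],
                           cfg$loss$alpha_vec, cfg$loss$gamma, cfg$loss$eps)
    }
    if (!is.finite(lg$loss))
      stop("training diverged: non-finite loss (try a lower learning rate)",
           call. = FALSE)
    grads <- .modelBackwardBatch(lg$dLogits, fw, params, cfg)
    clip <- cfg$train$clip %||% Inf
    if (is.finite(clip)) {
      gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
      if (gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
    }
    upd <- .adamwStep(params, grads, state, cfg$train$lr,
                      cfg$train$weight_decay)
    params <- upd$params
    state <- upd$state
    lossSum <- lossSum + lg$loss
    nb <- nb + 1L
  }
  list(params = params, state = state, loss = lossSum / nb)
}

.evalOn <- function(encsT, target, params, cfg, mode, batchSize = 64L) {
  n <- length(encsT)
  probs <- NULL
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1L, n)
    fw <- .modelForwardBatch(encsT[idx], params, cfg, mode, training = FALSE)
    probs <- rbind(probs, fw$probs)
  }
  if (mode == "single") {
    loss <- focalLossMulticlass(probs, target, cfg$loss$alpha,
                                cfg$loss$gamma, cfg$loss$eps)
    yPred <- max.col(probs, ties.method = "first")
    counts <- confusionCounts(target, yPred, ncol(probs))
    list(probs = probs, loss = loss, acc = mean(yPred == target),
         maF1 = macroF1(counts))
  } else {
    loss <- focalLossMultilabel(probs, target, cfg$loss$alpha_vec,
                                cfg$loss$gamma, cfg$loss$eps)
    pred <- (probs >= 0.5) * 1L
    ## multi-label macro F1 over classes
    tp <- colSums(pred == 1 & target == 1)
    fp <- colSums(pred == 1 & target == 0)
    fn <- colSums(pred == 0 & target == 1)
    f1 <- .safeDiv(2 * tp, 2 * tp + fp + fn)
    list(probs = probs, loss = loss, acc = mean(pred == target),
         maF1 = mean(f1))
  }
}

#' Train a localization model
#'
#' Minimizes the configured focal loss with AdamW, recording per-epoch
#' training loss and validation loss/accuracy/macro F1, and returns the
#' parameters of the epoch with the best validation macro F1 (early
#' stopping with the configured patience). Fully deterministic given
#' \code{config$train$seed}.
#'
#' @param train A \linkS4class{LocDataset}.
#' @param valid Optional validation \linkS4class{LocDataset}; without it the
#'   final-epoch parameters are kept and no early stopping happens.
#' @param config Configuration from \code{\link{locNetConfig}}.
#' @param verbose Print per-epoch progress?
#' @return A trained \linkS4class{LocModel}.
#' @export
trainLocModel <- function(train, valid = NULL, config = locNetConfig(),
                          verbose = FALSE) {
  mode <- labelMode(train)
  cls <- classNames(train)
  encsT <- .encodeInput(train, max(config$cm$kernel_sizes))
  target <- .datasetTargets(train)
  vEncsT <- if (!is.null(valid)) .encodeInput(valid, max(config$cm$kernel_sizes))
  vTarget <- if (!is.null(valid)) .datasetTargets(valid)
  withSeed(config$train$seed, {
    params <- .initLocParams(config, length(cls))
    state <- .adamwInit(params)
    hist <- NULL
    best <- list(maF1 = -Inf, params = params, epoch = 0L)
    bad <- 0L
    for (ep in seq_len(config$train$epochs)) {
      res <- .runEpoch(encsT, target, params, state, config, mode)
      params <- res$params
      state <- res$state
      row <- data.frame(epoch = ep, train_loss = res$loss,
                        valid_loss = NA_real_, valid_acc = NA_real_,
                        valid_maF1 = NA_real_)
      if (!is.null(valid)) {
        ev <- .evalOn(vEncsT, vTarget, params, config, mode)
        row$valid_loss <- ev$loss
        row$valid_acc <- ev$acc
        row$valid_maF1 <- ev$maF1
        if (ev$maF1 > best$maF1 + 1e-12) {
          best <- list(maF1 = ev$maF1, params = params, epoch = ep)
          bad <- 0L
        } else bad <- bad + 1L
      }
      hist <- rbind(hist, row)
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f%s", ep, res$loss,
                        if (!is.null(valid))
                          sprintf(", valid maF1 %.4f", row$valid_maF1)
                        else ""))
      if (!is.null(valid) && bad >= config$train$patience) break
    }
    finalParams <- if (!is.null(valid) && best$epoch > 0L) best$params
                   else params
    new("LocModel", config = config, params = finalParams, classNames = cls,
        labelMode = mode, history = hist)
  })
}

#' Stratified k-fold cross-validation
#'
#' Trains on k-1 folds (the held-out fold doubling as the early-stopping
#' validation set) and evaluates the full metrics panel on the held-out
#' fold, k times.
#'
#' @param dataset A \linkS4class{LocDataset}.
#' @param config Configuration from \code{\link{locNetConfig}}.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment; fold f trains with seed
#'   \code{config$train$seed + f - 1}.
#' @param verbose Print progress?
#' @return List of class \code{"LocCV"}: \code{folds} (assignment),
#'   \code{reports} (per-fold \code{MetricsReport}), \code{summary}
#'   (data.frame of mean and sd per metric), \code{models}.
#' @export
crossValidate <- function(dataset, config = locNetConfig(), k = 5L,
                          seed = 1L, verbose = FALSE) {
  fold <- stratifiedFolds(labels(dataset), k = k, seed = seed)
  reports <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- dataset[fold != f]
    te <- dataset[fold == f]
    cfgF <- config
    cfgF$train$seed <- config$train$seed + f - 1L
    if (verbose) message(sprintf("fold %d/%d (train %d, test %d)", f, k,
                                 length(tr), length(te)))
    m <- trainLocModel(tr, valid = te, config = cfgF, verbose = verbose)
    probs <- predictProbs(m, te)
    reports[[f]] <- computeMetrics(probs, .datasetTargets(te),
                                   classNames(dataset))
    models[[f]] <- m
  }
  metricNames <- c("acc", "macro_precision", "macro_recall", "macro_f1",
                   "macro_mcc", "mi_auc", "ma_auc", "mi_auprc")
  vals <- sapply(metricNames,
                 function(nm) vapply(reports, function(r) r[[nm]], 0))
  summ <- data.frame(metric = metricNames,
                     mean = colMeans(vals),
                     sd = apply(vals, 2L, stats::sd),
                     row.names = NULL)
  out <- list(folds = fold, reports = reports, summary = summ,
              models = models, k = k)
  class(out) <- "LocCV"
  out
}

#' @export
print.LocCV <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  with(x$summary,
       cat(paste(sprintf("  %-16s %.3f ± %.3f", metric, mean, sd),
                 collapse = "\n"), "\n"))
  invisible(x)
}

#' Grid search over hyperparameters
#'
#' Exhaustive (or budget-truncated, in declared order) evaluation of a
#' hyperparameter grid by cross-validated macro F1. Axis names are
#' dot-paths into the configuration (\code{"train.batch_size"},
#' \code{"lsta.heads"}, ...); an axis value may itself be a vector (e.g. a
#' CM kernel-size pair), in which case wrap the candidates in a list.
#'
#' @param dataset A \linkS4class{LocDataset}.
#' @param grid Named list of axes; default mirrors the published search
#'   space (batch size, paired CM kernel sizes, CM kernel counts, final
#'   pooling size, attention heads).
#' @param config Base configuration.
#' @param k,seed Cross-validation settings.
#' @param budget Maximum number of configurations to evaluate.
#' @param verbose Print progress?
#' @return List with \code{best} (configuration list), \code{bestScore} and
#'   \code{leaderboard} (data.frame, one row per evaluated configuration,
#'   sorted by mean maF1 with ties broken by grid order).
#' @export
gridSearch <- function(dataset, grid = defaultGridSpec(),
                       config = locNetConfig(), k = 5L, seed = 1L,
                       budget = Inf, verbose = FALSE) {
  .assert(length(grid) > 0L && all(lengths(grid) > 0L),
          "grid axes must be nonempty")
  combos <- expand.grid(lapply(grid, seq_along), KEEP.OUT.ATTRS = FALSE)
  nEval <- min(nrow(combos), budget)
  rows <- vector("list", nEval)
  configs <- vector("list", nEval)
  scores <- numeric(nEval)
  for (ci in seq_len(nEval)) {
    cfg <- config
    desc <- character(length(grid))
    for (ai in seq_along(grid)) {
      val <- grid[[ai]][[combos[ci, ai]]]
      cfg <- .setConfigPath(cfg, names(grid)[ai], val)
      desc[ai] <- sprintf("%s=%s", names(grid)[ai],
                          paste(val, collapse = "+"))
    }
    .validateLocNetConfig(cfg)
    if (verbose) message(sprintf("grid %d/%d: %s", ci, nEval,
                                 paste(desc, collapse = ", ")))
    cv <- crossValidate(dataset, cfg, k = k, seed = seed)
    scores[ci] <- cv$summary$mean[cv$summary$metric == "macro_f1"]
    configs[[ci]] <- cfg
    rows[[ci]] <- data.frame(rank = NA_integer_,
                             config = paste(desc, collapse = ", "),
                             mean_maF1 = scores[ci],
                             sd_maF1 = cv$summary$sd[cv$summary$metric ==
                                                       "macro_f1"])
  }
  lb <- do.call(rbind, rows)
  ord <- order(-lb$mean_maF1, seq_len(nEval))  # ties: earlier grid order wins
  lb <- lb[ord, ]
  lb$rank <- seq_len(nEval)
  bestIdx <- ord[1L]
  list(best = configs[[bestIdx]], bestScore = scores[bestIdx],
       leaderboard = lb)
}

.setConfigPath <- function(cfg, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) cfg[[parts]] <- value
  else if (length(parts) == 2L) cfg[[parts[1L]]][[parts[2L]]] <- value
  else stop("config paths have at most two components")
  cfg
}

#' Published hyperparameter search space
#'
#' Batch size, paired CM kernel sizes (searched as 2-combinations of the
#' single-kernel candidates 3..7), CM kernel counts, final adaptive-pooling
#' size (stages use 4P/2P/P), and attention heads.
#'
#' @return Named list of grid axes for \code{\link{gridSearch}}.
#' @export
defaultGridSpec <- function() {
  kerns <- utils::combn(c(3L, 4L, 5L, 6L, 7L), 2L, simplify = FALSE)
  pools <- lapply(c(64L, 128L, 256L), function(p) c(4L * p, 2L * p, p))
  counts <- lapply(c(32L, 64L, 128L), function(s) c(s, s, max(s %/% 2L, 8L)))
  list(`train.batch_size` = list(128L, 256L, 512L),
       `cm.kernel_sizes` = kerns,
       `cm.stage_filters` = counts,
       `cm.pool_targets` = pools,
       `lsta.heads` = list(2L, 4L, 6L, 8L))
}
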