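## Model assembly: parameter initialization, the full batched forward and
## backward passes across both kernel branches, and prediction helpers.
## Per-branch tower: CM encoder -> {LSTA, Bi-LSTM} -> fuse -> TextCNN.
## The two pooled branch vectors feed a single fully connected output layer.

.initLocParams <- function(cfg, nClasses) {
  cm <- cfg$cm
  d <- cm$stage_filters[3L]
  N <- cfg$lsta$heads
  dk <- cfg$lsta$d_k
  r <- cfg$lsta$rank
  H <- cfg$bilstm$hidden
  Fo <- cfg$textcnn$filters
  cinT <- d + 2L * H
  p <- list()
  for (i in seq_along(cm$kernel_sizes)) {
    pre <- paste0("b", i)
    k <- cm$kernel_sizes[i]
    cin <- c(8L, cm$stage_filters[1:2])
    for (s in 1:3) {
      p[[paste0(pre, "_conv", s, "_W")]] <- .initConvW(cm$stage_filters[s],
                                                       cin[s], k)
      p[[paste0(pre, "_conv", s, "_b")]] <- numeric(cm$stage_filters[s])
    }
    la <- paste0(pre, "_lsta")
    p[[paste0(la, "_Wq")]] <- .initMat(d, N * dk, d)
    p[[paste0(la, "_Wk")]] <- .initMat(d, N * dk, d)
    p[[paste0(la, "_Wv")]] <- .initMat(d, N * dk, d)
    if (r > 0L) {
      p[[paste0(la, "_Wp")]] <- array(rnorm(dk * r * N, sd = sqrt(1 / dk)),
                                      dim = c(dk, r, N))
      for (nm in c("sk", "sv", "lk", "lv")) {
        p[[paste0(la, "_ln_", nm, "_g")]] <- rep(1, dk)
        p[[paste0(la, "_ln_", nm, "_b")]] <- numeric(dk)
      }
    }
    p[[paste0(la, "_Wo")]] <- .initMat(N * dk, d, N * dk)
    p[[paste0(la, "_bo")]] <- numeric(d)
    lm <- paste0(pre, "_lstm")
    for (dir in c("f", "b")) {
      p[[paste0(lm, "_", dir, "_Wx")]] <- .initMat(d, 4L * H, d)
      p[[paste0(lm, "_", dir, "_Wh")]] <- .initMat(H, 4L * H, H)
      ## forget-gate bias starts at 1 (standard recipe: remember by default)
      p[[paste0(lm, "_", dir, "_b")]] <- c(numeric(H), rep(1, H),
                                           numeric(2L * H))
    }
    for (ti in seq_along(cfg$textcnn$kernel_sizes)) {
      tk <- cfg$textcnn$kernel_sizes[ti]
      p[[paste0(pre, "_tc", ti, "_W")]] <- .initConvW(Fo, cinT, tk)
      p[[paste0(pre, "_tc", ti, "_b")]] <- numeric(Fo)
    }
  }
  zWidth <- length(cm$kernel_sizes) * length(cfg$textcnn$kernel_sizes) * Fo
  ## zero-init output layer: training starts from the uniform prediction
  p$head_W <- matrix(0, zWidth, nClasses)
  p$head_b <- numeric(nClasses)
  p
}

#' Initialize an untrained localization model
#'
#' @param config Configuration from \code{\link{locNetConfig}}.
#' @param classNames Output class vocabulary.
#' @param labelMode \code{"single"} (softmax output) or \code{"multi"}
#'   (sigmoid output).
#' @param seed Seed for the parameter initialization.
#' @return A \linkS4class{LocModel} with random weights.
#' @export
initLocModel <- function(config = locNetConfig(),
                         classNames = lncCompartments(),
                         labelMode = c("single", "multi"), seed = 1L) {
  labelMode <- match.arg(labelMode)
  params <- withSeed(seed, .initLocParams(config, length(classNames)))
  new("LocModel", config = config, params = params, classNames = classNames,
      labelMode = labelMode,
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           valid_loss = numeric(), valid_acc = numeric(),
                           valid_maF1 = numeric()))
}

## Full batched forward. encsT: list of 8 x L matrices (channels first).
.modelForwardBatch <- function(encsT, params, cfg, mode, training) {
  B <- length(encsT)
  cm <- cfg$cm
  P <- cm$pool_targets[3L]
  d <- cm$stage_filters[3L]
  branches <- vector("list", length(cm$kernel_sizes))
  pooled <- vector("list", length(cm$kernel_sizes))
  for (i in seq_along(cm$kernel_sizes)) {
    pre <- paste0("b", i)
    cmcfg <- cm
    cmcfg$kernel <- cm$kernel_sizes[i]
    cmFws <- vector("list", B)
    Xarr <- array(0, dim = c(B, P, d))
    for (b in seq_len(B)) {
      fw <- .cmForwardOne(encsT[[b]], params, pre, cm, training)
      cmFws[[b]] <- fw
      Xarr[b, , ] <- fw$out
    }
    lstaFw <- .lstaBatchForward(Xarr, params, paste0(pre, "_lsta"),
                                cfg$lsta, training)
    Aarr <- lstaFw$out
    bl <- .bilstmForward(Xarr, params, paste0(pre, "_lstm"), cfg$bilstm,
                         training)
    Farr <- array(c(Aarr, bl$out), dim = c(B, P, d + dim(bl$out)[3L]))
    tc <- .textcnnForwardBatch(Farr, params, paste0(pre, "_tc"),
                               cfg$textcnn, training)
    pooled[[i]] <- tc$out
    branches[[i]] <- list(cmFws = cmFws, lstaFw = lstaFw, bl = bl, tc = tc)
  }
  Z <- do.call(cbind, pooled)
  hf <- .headForward(Z, params, cfg$textcnn, mode, training)
  list(probs = hf$probs, logits = hf$logits,
       cache = list(branches = branches, head = hf$cache, B = B, P = P,
                    d = d))
}

.modelBackwardBatch <- function(dLogits, fw, params, cfg) {
  cc <- fw$cache
  hb <- .headBackward(dLogits, params, cc$head)
  grads <- hb$grads
  wBranch <- length(cfg$textcnn$kernel_sizes) * cfg$textcnn$filters
  P <- cc$P
  d <- cc$d
  B <- cc$B
  for (i in seq_along(cfg$cm$kernel_sizes)) {
    pre <- paste0("b", i)
    br <- cc$branches[[i]]
    dPooled <- hb$dZ[, (i - 1L) * wBranch + seq_len(wBranch), drop = FALSE]
    tb <- .textcnnBackwardBatch(dPooled, params, paste0(pre, "_tc"),
                                cfg$textcnn, br$tc)
    grads <- .addGrads(grads, tb$grads)
    dAarr <- tb$dFarr[, , seq_len(d), drop = FALSE]
    dHarr <- tb$dFarr[, , d + seq_len(dim(tb$dFarr)[3L] - d), drop = FALSE]
    bb <- .bilstmBackward(dHarr, br$bl$cache, paste0(pre, "_lstm"))
    grads <- .addGrads(grads, bb$grads)
    dXarr <- bb$dXarr
    lb <- .lstaBatchBackward(dAarr, br$lstaFw, params,
                             paste0(pre, "_lsta"), cfg$lsta)
    grads <- .addGrads(grads, lb$grads)
    dXarr <- dXarr + lb$dX
    for (b in seq_len(B)) {
      cg <- .cmBackwardOne(matrix(dXarr[b, , ], P, d), br$cmFws[[b]], pre)
      grads <- .addGrads(grads, cg)
    }
  }
  grads
}

## Coerce assorted sequence inputs to a list of 8 x L encoded matrices.
.encodeInput <- function(x, minKernel = 5L) {
  if (is(x, "LocDataset")) x <- sequences(x)
  if (is(x, "DNAStringSet")) x <- as.character(x)
  if (is.character(x)) x <- lapply(x, encodeSequence, minLength = minKernel)
  if (is.matrix(x)) x <- list(x)
  lapply(x, function(m) {
    .assert(ncol(m) == 8L, "encoded sequences must be L x 8")
    t(m)
  })
}

#' Predict class probabilities
#'
#' Evaluation-mode forward pass of the full network.
#'
#' @param model A \linkS4class{LocModel}.
#' @param x Sequences: \linkS4class{LocDataset}, \code{DNAStringSet},
#'   character vector, or list of L x 8 encoded matrices.
#' @param batchSize Sequences per forward batch.
#' @return Numeric matrix, sequences x classes. Rows sum to 1 in
#'   single-label mode; entries are independent probabilities in multi-label
#'   mode.
#' @export
predictProbs <- function(model, x, batchSize = 64L) {
  encsT <- .encodeInput(x, max(model@config$cm$kernel_sizes))
  n <- length(encsT)
  out <- matrix(NA_real_, n, length(model@classNames),
                dimnames = list(NULL, model@classNames))
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1L, n)
    fw <- .modelForwardBatch(encsT[idx], model@params, model@config,
                             model@labelMode, training = FALSE)
    out[idx, ] <- fw$probs
  }
  out
}

#' Predict localization labels
#'
#' @param model A \linkS4class{LocModel}.
#' @param x Sequences (see \code{\link{predictProbs}}).
#' @param ids Optional sequence ids (taken from names when omitted).
#' @param batchSize Sequences per forward batch.
#' @return A data.frame: id, one probability column per class, and
#'   \code{predicted} (argmax class, or comma-joined classes scoring >= 0.5
#'   in multi-label mode).
#' @export
predictLoc <- function(model, x, ids = NULL, batchSize = 64L) {
  if (is.null(ids)) {
    ids <- if (is(x, "LocDataset")) names(sequences(x))
           else if (is(x, "DNAStringSet") || is.character(x)) names(x)
           else names(x)
  }
  probs <- predictProbs(model, x, batchSize)
  ids <- ids %||% sprintf("seq%d", seq_len(nrow(probs)))
  predicted <- if (model@labelMode == "single") {
    model@classNames[max.col(probs, ties.method = "first")]
  } else {
    apply(probs, 1L, function(p) {
      hit <- model@classNames[p >= 0.5]
      if (length(hit)) paste(hit, collapse = ",")
      else model@classNames[which.max(p)]
    })
  }
  data.frame(id = ids, probs, predicted = predicted, check.names = FALSE)
}

#' @describeIn predictLoc S4 predict method.
#' @param object A \linkS4class{LocModel}.
#' @param ... Passed on to \code{predictLoc}.
#' @export
setMethod("predict", "LocModel", function(object, ...) predictLoc(object, ...))

#' Write predictions as TSV
#' @param pred Data frame from \code{\link{predictLoc}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(pred, path) {
  write.table(pred, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
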