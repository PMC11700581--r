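## TextCNN head: parallel 1D convolutions of kernel sizes 1/3/5 over the
## fused positions x channels map, ReLU, then a global max pool per filter.
## The two branch vectors are concatenated and classified by a single fully
## connected layer (softmax single-label / sigmoid multi-label).

#' Output length of a 1D convolution
#'
#' \code{Lout = floor((Lin + 2*padding - (kernelsize - 1) - 1) / stride) + 1}.
#'
#' @param Lin Input length.
#' @param padding Zero padding added on each side.
#' @param kernelsize Sliding window size.
#' @param stride Step of the sliding window.
#' @return The output length (error if nonpositive).
#' @examples
#' convOutLength(128, 0, 3, 1)  # 126
#' @export
convOutLength <- function(Lin, padding = 0L, kernelsize = 3L, stride = 1L) {
  out <- floor((Lin + 2 * padding - (kernelsize - 1) - 1) / stride) + 1
  .assert(out >= 1, "convolution output length %d is nonpositive", out)
  as.integer(out)
}

## Batched conv over a B x P x Cin array for one kernel; returns the pooled
## B x F matrix plus cache. Supports the configured padding/stride through
## zero padding and column subsampling of the dense stride-1 convolution.
.textcnnKernelForward <- function(Farr, W, b, padding, stride) {
  B <- dim(Farr)[1L]; P <- dim(Farr)[2L]; Cin <- dim(Farr)[3L]
  k <- dim(W)[3L]
  Fo <- dim(W)[1L]
  if (padding > 0L) {
    pad <- array(0, dim = c(B, P + 2L * padding, Cin))
    pad[, padding + seq_len(P), ] <- Farr
    Farr <- pad
    P <- P + 2L * padding
  }
  Ld <- P - k + 1L                       # dense (stride 1) output length
  sel <- seq(1L, Ld, by = stride)        # strided output positions
  Lout <- length(sel)
  Wflat <- W
  dim(Wflat) <- c(Fo, Cin * k)
  conv <- cpp_textcnn_conv(Farr, dim(Farr), Wflat, b, k, sel)
  ## ReLU then global max over positions per (sequence, filter), computed
  ## as max-then-ReLU (identical: ReLU is monotone)
  bm <- cpp_blockmax(conv, B, Lout)
  pooled <- .relu(bm$out)
  amax <- bm$amax
  list(out = pooled,
       cache = list(Farr = Farr, pooled = pooled, amax = amax, sel = sel,
                    k = k, B = B, Lout = Lout, Cin = Cin, Fo = Fo,
                    padding = padding, Pin = dim(Farr)[2L]))
}

.textcnnKernelBackward <- function(dPooled, W, cache) {
  ## gradients flow only through the argmax of the global max pool, so the
  ## backward is sparse: one window per (sequence, filter)
  bw <- cpp_textcnn_bw(dPooled, cache$amax, cache$pooled,
                       as.vector(cache$Farr), dim(cache$Farr),
                       as.vector(W), dim(W), cache$sel)
  dFarr <- bw$dFarr
  if (cache$padding > 0L) {
    P <- cache$Pin - 2L * cache$padding
    dFarr <- dFarr[, cache$padding + seq_len(P), , drop = FALSE]
  }
  list(dFarr = dFarr, dW = bw$dW, db = bw$db)
}

## All three kernels of one branch; pooled vectors concatenated -> B x 3F.
.textcnnForwardBatch <- function(Farr, params, prefix, cfg, training) {
  ks <- cfg$kernel_sizes
  outs <- vector("list", length(ks))
  caches <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    kf <- .textcnnKernelForward(Farr,
                                params[[paste0(prefix, i, "_W")]],
                                params[[paste0(prefix, i, "_b")]],
                                cfg$padding, cfg$stride)
    outs[[i]] <- kf$out
    caches[[i]] <- kf$cache
  }
  list(out = do.call(cbind, outs), caches = caches)
}

.textcnnBackwardBatch <- function(dOut, params, prefix, cfg, fw) {
  ks <- cfg$kernel_sizes
  Fo <- cfg$filters
  grads <- list()
  dFarr <- NULL
  for (i in seq_along(ks)) {
    dPooled <- dOut[, (i - 1L) * Fo + seq_len(Fo), drop = FALSE]
    bw <- .textcnnKernelBackward(dPooled, params[[paste0(prefix, i, "_W")]],
                                 fw$caches[[i]])
    grads[[paste0(prefix, i, "_W")]] <- bw$dW
    grads[[paste0(prefix, i, "_b")]] <- bw$db
    dFarr <- if (is.null(dFarr)) bw$dFarr else dFarr + bw$dFarr
  }
  list(dFarr = dFarr, grads = grads)
}

#' Run the TextCNN feature extractor
#'
#' Evaluation-mode forward of one branch's TextCNN on a positions x channels
#' map: three parallel 1D convolutions (kernel sizes 1/3/5 by default),
#' ReLU, global max pool per filter, pooled vectors concatenated.
#'
#' @param x Positions x channels matrix (128 x 64 under the defaults).
#' @param model A \linkS4class{LocModel}.
#' @param branch Branch index.
#' @return Numeric vector of length \code{3 * filters}.
#' @export
textcnnForward <- function(x, model, branch = 1L) {
  Farr <- array(x, dim = c(1L, nrow(x), ncol(x)))
  res <- .textcnnForwardBatch(Farr, model@params,
                              paste0("b", branch, "_tc"),
                              model@config$textcnn, training = FALSE)
  drop(res$out)
}

## ---- classification head ---------------------------------------------------

.headForward <- function(Z, params, cfg, mode, training) {
  dr <- .dropoutForward(Z, cfg$dropout, training)
  logits <- sweep(dr$out %*% params$head_W, 2L, params$head_b, "+")
  probs <- if (mode == "single") .softmaxRows(logits) else .sigmoid(logits)
  list(probs = probs, logits = logits,
       cache = list(Zdrop = dr$out, mask = dr$mask))
}

.headBackward <- function(dLogits, params, cache) {
  grads <- list(head_W = t(cache$Zdrop) %*% dLogits,
                head_b = colSums(dLogits))
  dZ <- .dropoutBackward(dLogits %*% t(params$head_W), cache$mask)
  list(dZ = dZ, grads = grads)
}

#' Classify pooled branch feature vectors
#'
#' Concatenates the pooled TextCNN vectors of the two kernel branches and
#' applies the fully connected output layer: softmax over classes in
#' single-label mode, element-wise sigmoid in multi-label mode.
#'
#' @param branchVectors List of pooled vectors, one per branch.
#' @param model A \linkS4class{LocModel}.
#' @return List with \code{scores} (per-class probabilities) and
#'   \code{predicted} (class name, or character vector of classes whose
#'   sigmoid score exceeds 0.5, with the top class as fallback).
#' @export
classify <- function(branchVectors, model) {
  z <- matrix(unlist(branchVectors), nrow = 1L)
  .assert(ncol(z) == nrow(model@params$head_W),
          "pooled width %d does not match the head (%d)", ncol(z),
          nrow(model@params$head_W))
  hf <- .headForward(z, model@params, model@config$textcnn,
                     model@labelMode, training = FALSE)
  scores <- drop(hf$probs)
  names(scores) <- model@classNames
  predicted <- if (model@labelMode == "single") {
    model@classNames[which.max(scores)]
  } else {
    hit <- model@classNames[scores >= 0.5]
    if (length(hit)) hit else model@classNames[which.max(scores)]
  }
  list(scores = scores, predicted = predicted)
}
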