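## 1D convolution (valid, stride 1) and adaptive max pooling — the building
## blocks of the CM encoder that maps an arbitrary-length sequence onto a
## fixed-size feature map without padding or truncation.

## Valid 1D convolution. X: Cin x L (channels first); W: Cout x Cin x k;
## b: length Cout. Output: Cout x (L - k + 1). Computed as a sum of k
## offset matrix products rather than im2col: fewer copies, same BLAS.
.conv1dForward <- function(X, W, b) {
  dw <- dim(W)
  .assert(ncol(X) >= dw[3L], "input has %d positions but the kernel needs %d",
          ncol(X), dw[3L])
  Wflat <- W
  dim(Wflat) <- c(dw[1L], dw[2L] * dw[3L])  # free view: layout is (o, c, j)
  cpp_conv1d_fw(X, Wflat, b, dw[3L])
}

.conv1dBackward <- function(X, W, dOut, needInputGrad = TRUE) {
  dw <- dim(W)
  Wflat <- W
  dim(Wflat) <- c(dw[1L], dw[2L] * dw[3L])
  bw <- cpp_conv1d_bw(X, Wflat, dOut, dw[3L], needInputGrad)
  dim(bw$dW) <- dw
  list(dX = bw$dX, dW = bw$dW, db = drop(bw$db))
}

## Adaptive max-pool bin boundaries (0-based spec: bin i covers input
## indices floor(i*L/T) .. ceil((i+1)*L/T) - 1). Bins may overlap or repeat
## elements when L < T. Boundaries are memoized per (L, T).
.poolCache <- new.env(parent = emptyenv())

.poolIndex <- function(L, target) {
  key <- paste0(L, "_", target)
  hit <- .poolCache[[key]]
  if (!is.null(hit)) return(hit)
  i <- seq_len(target) - 1
  res <- list(starts = as.integer(floor(i * L / target) + 1),
              ends = as.integer(ceiling((i + 1) * L / target)))
  .poolCache[[key]] <- res
  res
}

.adaptiveMaxPoolForward <- function(X, target, relu = FALSE) {
  px <- .poolIndex(ncol(X), target)
  mp <- cpp_adaptive_maxpool(X, px$starts, px$ends, relu)
  list(out = mp$out, amax = mp$amax, L = ncol(X))
}

.adaptiveMaxPoolBackward <- function(dOut, amax, L) {
  cpp_maxpool_bw(dOut, amax, L)
}

#' Adaptive max pooling to a fixed number of positions
#'
#' Pools a channels x positions feature map to exactly \code{target}
#' positions per channel. Bin \code{i} (0-based) covers input positions
#' \code{floor(i*L/target)} through \code{ceiling((i+1)*L/target) - 1}
#' (half-open), so the operator is defined for any input length, including
#' \code{L < target} where bins repeat elements.
#'
#' @param x Numeric matrix, channels x positions.
#' @param target Positive integer, output positions per channel.
#' @return Channels x \code{target} matrix of bin maxima.
#' @examples
#' adaptiveMaxPool(matrix(c(1, 2), 1), 4)  # 1 2 -> 1 1 2 2
#' @export
adaptiveMaxPool <- function(x, target) {
  .assert(is.matrix(x) && ncol(x) >= 1L, "x must be a matrix with >= 1 position")
  .assert(length(target) == 1L && target >= 1, "target must be >= 1")
  .adaptiveMaxPoolForward(x, as.integer(target))$out
}

## ---- CM encoder ------------------------------------------------------------

## One conv -> ReLU -> adaptive-max-pool -> dropout stage. Computed as
## conv -> pool -> ReLU (identical: ReLU is monotone, so pooling commutes
## with it), which keeps the large pre-pool activation out of the cache.
.cmStageForward <- function(X, W, b, target, pdrop, training) {
  conv <- .conv1dForward(X, W, b)
  pool <- .adaptiveMaxPoolForward(conv, target, relu = TRUE)
  drop <- .dropoutForward(pool$out, pdrop, training)
  list(out = drop$out,
       cache = list(X = X, W = W, poolOut = pool$out, amax = pool$amax,
                    Lact = ncol(conv), mask = drop$mask))
}

.cmStageBackward <- function(dOut, cache, needInputGrad = TRUE) {
  dAct <- .dropoutBackward(dOut, cache$mask)
  dPool <- dAct * (cache$poolOut > 0)
  dConv <- .adaptiveMaxPoolBackward(dPool, cache$amax, cache$Lact)
  bw <- .conv1dBackward(cache$X, cache$W, dConv, needInputGrad)
  list(dX = bw$dX, dW = bw$dW, db = bw$db)
}

## Full single-branch CM encoder on one sequence. X: 8 x L. Returns the
## positions-first P x C interface map (default 128 x 32).
.cmForwardOne <- function(X, params, prefix, cfg, training) {
  caches <- vector("list", 3L)
  cur <- X
  for (s in 1:3) {
    st <- .cmStageForward(cur,
                          params[[paste0(prefix, "_conv", s, "_W")]],
                          params[[paste0(prefix, "_conv", s, "_b")]],
                          cfg$pool_targets[s], cfg$dropout, training)
    caches[[s]] <- st$cache
    cur <- st$out
  }
  list(out = t(cur), caches = caches)
}

.cmBackwardOne <- function(dOutPC, fw, prefix) {
  grads <- list()
  d <- t(dOutPC)
  for (s in 3:1) {
    bw <- .cmStageBackward(d, fw$caches[[s]], needInputGrad = s > 1L)
    grads[[paste0(prefix, "_conv", s, "_W")]] <- bw$dW
    grads[[paste0(prefix, "_conv", s, "_b")]] <- bw$db
    d <- bw$dX
  }
  grads
}

#' Run the convolution/adaptive-pooling encoder
#'
#' Maps an encoded sequence (L x 8) through the two kernel branches of the
#' CM encoder (three conv + ReLU + adaptive-max-pool stages each) to two
#' fixed-size feature maps, positions x channels (128 x 32 under the default
#' configuration) regardless of L. Evaluation mode: no dropout.
#'
#' @param enc L x 8 encoded sequence (see \code{\link{encodeSequence}}).
#' @param model A \linkS4class{LocModel}.
#' @return A list with one positions x channels matrix per kernel branch.
#' @export
cmForward <- function(enc, model) {
  cfg <- model@config$cm
  .assert(ncol(enc) == 8L, "encoded input must be L x 8")
  X <- t(enc)
  out <- lapply(seq_along(cfg$kernel_sizes), function(i) {
    .cmForwardOne(X, model@params, paste0("b", i), cfg, training = FALSE)$out
  })
  names(out) <- paste0("k", cfg$kernel_sizes)
  out
}
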