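## Low-level numerical kernels shared by the network layers. Every forward
## returns the values needed by its backward in a `cache` list; backwards
## return gradients with the same shapes as their inputs/parameters. All of
## this is plain BLAS-backed base R.

.relu <- function(x) (x > 0) * x

.sigmoid <- function(x) 1 / (1 + exp(-x))

## Row-wise numerically stable softmax.
.softmaxRows <- function(x) {
  e <- exp(x - cpp_rowmax(x))
  e / rowSums(e)
}

## Column-wise softmax (used by the dynamic low-rank projection).
.softmaxCols <- function(x) {
  m <- apply(x, 2L, max)
  e <- exp(sweep(x, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

## Backward through row-wise softmax: given y = softmax(x) and dL/dy,
## dL/dx = y * (dy - rowSums(dy * y)).
.softmaxRowsBackward <- function(y, dy) {
  y * (dy - rowSums(dy * y))
}

.softmaxColsBackward <- function(y, dy) {
  y * sweep(dy, 2L, colSums(dy * y))
}

## Inverted dropout. Keeps expectation fixed so evaluation needs no rescale.
.dropoutForward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

.dropoutBackward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

## Layer normalization across rows (each row a feature vector).
.layerNormForward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

.layerNormBackward <- function(dout, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  d <- ncol(xhat)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2L, g, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

## Parameter initialization: He/Glorot-style scaled Gaussians.
.initMat <- function(nr, nc, fanIn) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)
}

.initConvW <- function(cout, cin, k) {
  array(rnorm(cout * cin * k, sd = sqrt(2 / (cin * k))), dim = c(cout, cin, k))
}

## ---- AdamW -----------------------------------------------------------------

.adamwInit <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

## Decoupled weight decay: p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p).
.adamwStep <- function(params, grads, state, lr, weightDecay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    ## in-place so vector parameters keep their (dim-less) shape
    params[[nm]][] <- params[[nm]] - lr * (upd + weightDecay * params[[nm]])
  }
  list(params = params, state = state)
}

## Elementwise sum of two gradient lists with identical structure.
.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

.zeroLike <- function(params) {
  lapply(params, function(p) {
    z <- p; z[] <- 0; z
  })
}
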