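## Long-short term attention (LSTA). Each head combines
##   * short-term attention: queries attend to keys inside their own
##     non-overlapping window segment (window w; with the default w = 128 and
##     the 128-position encoder interface this is full attention), and
##   * long-term attention: a dynamic low-rank projection that column-softmaxes
##     a learned P x r score matrix over positions and condenses the full
##     key/value set into r summary rows.
## The two branches are layer-normalized separately (dual normalization)
## before the keys/values are concatenated, scaled-dot-product attention is
## computed over the joint key set, and head outputs are mixed back to the
## model width. With rank r = 0 the long branch (and the dual normalization
## that exists only to reconcile the two branches) is disabled, giving plain
## windowed multi-head attention. The batched forward/backward live in
## compiled code (src/kernels.cpp); R holds the parameter plumbing.

## Non-overlapping segment windows covering P positions.
.lstaSegments <- function(P, w) {
  starts <- seq(1L, P, by = w)
  lapply(starts, function(s) s:min(s + w - 1L, P))
}

#' Short-term attention context of each query position
#'
#' Positions are partitioned into consecutive segments of length
#' \code{window} (the final segment may be partial); each query attends to
#' the keys of its own segment. Returned as the list of segments.
#'
#' @param P Number of positions.
#' @param window Segment length.
#' @return List of integer index vectors partitioning \code{1:P}.
#' @export
shortTermContext <- function(P, window) {
  .assert(P >= 1 && window >= 1, "P and window must be >= 1")
  .lstaSegments(as.integer(P), as.integer(window))
}

#' Dynamic low-rank projection of keys and values
#'
#' A score matrix \code{K \%*\% Wp} (P x r) is softmaxed over positions
#' (column-wise) to form projection weights; the projected keys and values
#' are \code{t(weights) \%*\% K} and \code{t(weights) \%*\% V} (r rows each).
#'
#' @param K,V P x d_k key and value matrices.
#' @param Wp d_k x r learned score weights.
#' @return List with \code{Kbar}, \code{Vbar} (r x d_k) and the projection
#'   \code{weights} (P x r, columns sum to 1).
#' @export
dynamicProjection <- function(K, V, Wp) {
  S <- K %*% Wp
  Pm <- .softmaxCols(S)
  list(Kbar = t(Pm) %*% K, Vbar = t(Pm) %*% V, weights = Pm)
}

## Gather one branch's LSTA parameters in the layout the kernels expect.
.lstaParamsFor <- function(params, prefix, cfg) {
  dk <- cfg$d_k
  r <- cfg$rank
  ln <- list()
  if (r > 0L) {
    for (nm in c("sk_g", "sk_b", "sv_g", "sv_b", "lk_g", "lk_b",
                 "lv_g", "lv_b"))
      ln[[nm]] <- params[[paste0(prefix, "_ln_", nm)]]
    Wp <- params[[paste0(prefix, "_Wp")]]
  } else {
    Wp <- array(0, dim = c(dk, 0L, cfg$heads))
  }
  list(Wq = params[[paste0(prefix, "_Wq")]],
       Wk = params[[paste0(prefix, "_Wk")]],
       Wv = params[[paste0(prefix, "_Wv")]],
       Wp = Wp, ln = ln,
       Wo = params[[paste0(prefix, "_Wo")]],
       bo = params[[paste0(prefix, "_bo")]])
}

## Batched forward over a B x P x d array. Returns the B x P x d output
## array and the opaque cache consumed by .lstaBatchBackward.
.lstaBatchForward <- function(Xarr, params, prefix, cfg, training) {
  pp <- .lstaParamsFor(params, prefix, cfg)
  res <- cpp_lsta_batch_fw(Xarr, dim(Xarr), pp$Wq, pp$Wk, pp$Wv, pp$Wp,
                           pp$ln, pp$Wo, pp$bo, cfg$d_k, cfg$rank,
                           cfg$window, cfg$dropout, training)
  list(out = res$out, cache = res$cache, training = training)
}

.lstaBatchBackward <- function(dArr, fw, params, prefix, cfg) {
  pp <- .lstaParamsFor(params, prefix, cfg)
  bw <- cpp_lsta_batch_bw(dArr, fw$cache, pp$Wq, pp$Wk, pp$Wv, pp$Wp,
                          pp$ln, pp$Wo, cfg$d_k, cfg$rank, cfg$dropout,
                          fw$training)
  grads <- stats::setNames(
    list(bw$dWq, bw$dWk, bw$dWv, bw$dWo, drop(bw$dbo)),
    paste0(prefix, c("_Wq", "_Wk", "_Wv", "_Wo", "_bo")))
  if (cfg$rank > 0L) {
    grads[[paste0(prefix, "_Wp")]] <- bw$dWp
    for (nm in names(bw$dln))
      grads[[paste0(prefix, "_ln_", nm)]] <- drop(bw$dln[[nm]])
  }
  list(dX = bw$dX, grads = grads)
}

## Single-sequence wrappers kept for the exported interface and unit tests.
.lstaForwardOne <- function(x, params, prefix, cfg, training) {
  fw <- .lstaBatchForward(array(x, dim = c(1L, nrow(x), ncol(x))), params,
                          prefix, cfg, training)
  list(out = matrix(fw$out[1L, , ], nrow(x)), fw = fw)
}

.lstaBackwardOne <- function(dOut, fwOne, params, prefix, cfg) {
  bw <- .lstaBatchBackward(array(dOut, dim = c(1L, nrow(dOut), ncol(dOut))),
                           fwOne$fw, params, prefix, cfg)
  list(dx = matrix(bw$dX[1L, , ], nrow(dOut)), grads = bw$grads)
}

#' Run the long-short term attention block
#'
#' Evaluation-mode forward (no dropout) of one branch's LSTA block on a
#' positions x channels feature map; output has the same shape.
#'
#' @param x Positions x channels matrix (128 x 32 under the defaults).
#' @param model A \linkS4class{LocModel}.
#' @param branch Branch index (1 = first CM kernel branch).
#' @return Positions x channels matrix.
#' @export
lstaForward <- function(x, model, branch = 1L) {
  cfg <- model@config$lsta
  .lstaForwardOne(x, model@params, paste0("b", branch, "_lsta"), cfg,
                  training = FALSE)$out
}

#' Attention weights of the long-short term attention block
#'
#' Evaluation-mode per-head attention matrices (queries x [short keys;
#' projected long keys]); rows sum to 1.
#'
#' @inheritParams lstaForward
#' @return List with one row-stochastic matrix per head.
#' @export
lstaAttentionWeights <- function(x, model, branch = 1L) {
  cfg <- model@config$lsta
  params <- model@params
  prefix <- paste0("b", branch, "_lsta")
  pp <- .lstaParamsFor(params, prefix, cfg)
  P <- nrow(x)
  dk <- cfg$d_k
  segs <- .lstaSegments(P, cfg$window)
  Q <- x %*% pp$Wq
  K <- x %*% pp$Wk
  V <- x %*% pp$Wv
  lapply(seq_len(cfg$heads), function(h) {
    ch <- (h - 1L) * dk + seq_len(dk)
    Kh <- K[, ch, drop = FALSE]
    Vh <- V[, ch, drop = FALSE]
    if (cfg$rank > 0L) {
      pj <- dynamicProjection(Kh, Vh, pp$Wp[, , h])
      lnK <- .layerNormForward(Kh, pp$ln$sk_g, pp$ln$sk_b)$out
      lnKb <- .layerNormForward(pj$Kbar, pp$ln$lk_g, pp$ln$lk_b)$out
    } else {
      lnK <- Kh
      lnKb <- NULL
    }
    A <- matrix(0, P, cfg$window + cfg$rank)
    for (rows in segs) {
      Kcat <- rbind(lnK[rows, , drop = FALSE], lnKb)
      a <- .softmaxRows((Q[rows, ch, drop = FALSE] %*% t(Kcat)) / sqrt(dk))
      A[rows, seq_len(ncol(a))] <- a
    }
    A
  })
}
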