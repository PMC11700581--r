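## Bidirectional LSTM over the fixed-length encoder interface, batched over
## sequences. Standard gate parameterization: sigmoid input/forget/output
## gates, tanh candidate, zero initial states:
##   C_t = f_t * C_{t-1} + i_t * tanh(Wcx x_t + Wch h_{t-1} + b_c)
##   h_t = o_t * tanh(C_t)
## Per-position output concatenates the forward and backward hidden states.
## The recurrence itself runs in compiled code (src/kernels.cpp).

## Bi-LSTM over B x P x Cin; output B x P x 2H with dropout on the output.
.bilstmForward <- function(Xarr, params, prefix, cfg, training) {
  pn <- paste0(prefix, c("_f_Wx", "_f_Wh", "_f_b", "_b_Wx", "_b_Wh", "_b_b"))
  res <- cpp_bilstm_fw(Xarr, dim(Xarr), params[[pn[1L]]], params[[pn[2L]]],
                       params[[pn[3L]]], params[[pn[4L]]], params[[pn[5L]]],
                       params[[pn[6L]]])
  dr <- .dropoutForward(res$out, cfg$dropout, training)
  list(out = dr$out,
       cache = list(ptr = res$cache, mask = dr$mask, pn = pn,
                    fWx = params[[pn[1L]]], fWh = params[[pn[2L]]],
                    bWx = params[[pn[4L]]], bWh = params[[pn[5L]]]))
}

.bilstmBackward <- function(dOut, cache, prefix) {
  dOut <- .dropoutBackward(dOut, cache$mask)
  bw <- cpp_bilstm_bw(dOut, cache$ptr, cache$fWx, cache$fWh, cache$bWx,
                      cache$bWh)
  grads <- stats::setNames(
    list(bw$f_Wx, bw$f_Wh, drop(bw$f_b), bw$b_Wx, bw$b_Wh, drop(bw$b_b)),
    cache$pn)
  list(dXarr = bw$dX, grads = grads)
}

#' Run the bidirectional LSTM block
#'
#' Evaluation-mode forward of one branch's Bi-LSTM on a positions x channels
#' feature map; per-position output concatenates the forward and backward
#' hidden states (width 2 x hidden = input width under the defaults).
#'
#' @param x Positions x channels matrix.
#' @param model A \linkS4class{LocModel}.
#' @param branch Branch index.
#' @return Positions x (2 * hidden) matrix.
#' @export
bilstmForward <- function(x, model, branch = 1L) {
  Xarr <- array(x, dim = c(1L, nrow(x), ncol(x)))
  res <- .bilstmForward(Xarr, model@params, paste0("b", branch, "_lstm"),
                        model@config$bilstm, training = FALSE)
  matrix(res$out[1L, , ], nrow(x))
}

#' Fuse attention and recurrent feature maps
#'
#' Channel-wise concatenation per position, order [attention; Bi-LSTM].
#'
#' @param lstaOut,bilstmOut Positions x channels matrices with equal
#'   position counts.
#' @return Positions x (sum of channels) matrix.
#' @export
fuseFeatures <- function(lstaOut, bilstmOut) {
  .assert(nrow(lstaOut) == nrow(bilstmOut),
          "position counts differ: %d vs %d", nrow(lstaOut), nrow(bilstmOut))
  cbind(lstaOut, bilstmOut)
}
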