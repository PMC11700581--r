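`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib RNALocNet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats runif rnorm setNames
#' @importFrom utils modifyList read.delim write.table head
NULL

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

## Run `expr` under a private RNG stream derived from `seed`, restoring the
## caller's RNG state afterwards. All stochastic entry points route through
## this so that a single integer seed reproduces a run byte-for-byte.
withSeed <- function(seed, expr) {
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
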