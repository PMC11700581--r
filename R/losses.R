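## Focal losses for imbalanced localization data. Natural logarithm
## throughout; probabilities are clamped at eps before the log so that a
## zero probability yields a large finite loss, never NaN.

#' Multi-class focal loss
#'
#' Mean over samples of \code{-alpha * (1 - p_true)^gamma * log(p_true)},
#' where \code{p_true} is the probability assigned to the true class. With
#' \code{gamma = 0, alpha = 1} this reduces exactly to cross-entropy.
#'
#' @param probs m x n row-stochastic probability matrix.
#' @param labels True classes: integer indices (1-based), or a factor whose
#'   levels match the columns of \code{probs}.
#' @param alpha Class-imbalance scaling factor.
#' @param gamma Focusing parameter (down-weights easy examples).
#' @param eps Probability clamp before the log.
#' @return Nonnegative scalar loss.
#' @examples
#' p <- matrix(c(0.5, 0.5), 1)
#' focalLossMulticlass(p, 1L)  # 0.25 * log(2)
#' @export
focalLossMulticlass <- function(probs, labels, alpha = 1, gamma = 2,
                                eps = 1e-8) {
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  .assert(!anyNA(y) && all(y >= 1L) && all(y <= ncol(probs)),
          "labels must be valid class indices")
  .assert(length(y) == nrow(probs), "labels must match rows of probs")
  p <- pmax(probs[cbind(seq_len(nrow(probs)), y)], eps)
  mean(-alpha * (1 - p)^gamma * log(p))
}

## Value + gradient wrt logits (through the softmax) for training.
.focalMulticlassGrad <- function(probs, y, alpha, gamma, eps = 1e-8) {
  m <- nrow(probs)
  p <- pmax(probs[cbind(seq_len(m), y)], eps)
  loss <- mean(-alpha * (1 - p)^gamma * log(p))
  ## d/dp of -alpha (1-p)^g log p = alpha [ g (1-p)^(g-1) log p - (1-p)^g / p ]
  dldp <- alpha * (gamma * (1 - p)^pmax(gamma - 1, 0) * log(p) -
                     (1 - p)^gamma / p) / m
  dProbs <- matrix(0, m, ncol(probs))
  dProbs[cbind(seq_len(m), y)] <- dldp
  dLogits <- .softmaxRowsBackward(probs, dProbs)
  list(loss = loss, dLogits = dLogits)
}

#' Multi-label focal loss
#'
#' Per class \code{i}: \code{FL_i = mean_samples(-alpha_i (1 - p_i)^gamma *
#' log(p_i))} with \code{p_i} the predicted sigmoid probability when the
#' label is 1 and its complement otherwise; the loss is the mean of
#' \code{FL_i} over the classes.
#'
#' @param probs m x n matrix of sigmoid outputs in [0, 1].
#' @param labels m x n binary matrix.
#' @param alphaVec Per-class scaling factors, length n.
#' @param gamma Focusing parameter.
#' @param eps Probability clamp before the log.
#' @return Nonnegative scalar loss.
#' @export
focalLossMultilabel <- function(probs, labels,
                                alphaVec = locNetConfig()$loss$alpha_vec,
                                gamma = 2, eps = 1e-8) {
  .assert(all(dim(probs) == dim(labels)), "probs and labels shapes differ")
  .assert(length(alphaVec) == ncol(probs),
          "alphaVec must have one entry per class")
  .assert(all(labels %in% c(0, 1)), "labels must be binary")
  p <- pmax(ifelse(labels == 1, probs, 1 - probs), eps)
  fl <- -(1 - p)^gamma * log(p)
  mean(colMeans(fl) * alphaVec)
}

## Value + gradient wrt logits (through the sigmoid) for training.
.focalMultilabelGrad <- function(probs, Y, alphaVec, gamma, eps = 1e-8) {
  m <- nrow(probs)
  n <- ncol(probs)
  p <- pmax(ifelse(Y == 1, probs, 1 - probs), eps)
  A <- matrix(alphaVec, m, n, byrow = TRUE)
  loss <- mean(colMeans(-A * (1 - p)^gamma * log(p)))
  dldp <- A * (gamma * (1 - p)^pmax(gamma - 1, 0) * log(p) -
                 (1 - p)^gamma / p) / (m * n)
  dldphat <- ifelse(Y == 1, dldp, -dldp)
  dLogits <- dldphat * probs * (1 - probs)
  list(loss = loss, dLogits = dLogits)
}
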