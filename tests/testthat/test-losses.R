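# Focal losses: worked values, analytic limits, and scalar-loop oracles.

## independent scalar-loop oracles
bruteFocalMulticlass <- function(probs, y, alpha, gamma, eps = 1e-8) {
  total <- 0
  for (i in seq_len(nrow(probs))) {
    p <- max(probs[i, y[i]], eps)
    total <- total - alpha * (1 - p)^gamma * log(p)
  }
  total / nrow(probs)
}

bruteFocalMultilabel <- function(probs, Y, alphaVec, gamma, eps = 1e-8) {
  n <- ncol(probs)
  fl <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (s in seq_len(nrow(probs))) {
      p <- if (Y[s, i] == 1) probs[s, i] else 1 - probs[s, i]
      p <- max(p, eps)
      acc <- acc - alphaVec[i] * (1 - p)^gamma * log(p)
    }
    fl[i] <- acc / nrow(probs)
  }
  mean(fl)
}

randProbRows <- function(m, n) {
  x <- matrix(rexp(m * n), m, n)
  x / rowSums(x)
}

test_that("multi-class focal loss reproduces hand-computed values", {
  # p_true = 1 -> 0
  expect_equal(focalLossMulticlass(matrix(c(1, 0), 1), 1L), 0)
  # p_true = 0.5, alpha = 1, gamma = 2 -> 0.25 ln 2
  expect_equal(focalLossMulticlass(matrix(c(0.5, 0.5), 1), 1L),
               0.25 * log(2), tolerance = 1e-12)
  expect_equal(0.25 * log(2), 0.173287, tolerance = 1e-5)
})

test_that("gamma = 0, alpha = 1 reduces exactly to cross-entropy", {
  set.seed(21)
  probs <- randProbRows(20, 5)
  y <- sample(5L, 20L, replace = TRUE)
  ce <- mean(-log(probs[cbind(1:20, y)]))
  expect_equal(focalLossMulticlass(probs, y, alpha = 1, gamma = 0), ce,
               tolerance = 1e-12)
})

test_that("focal loss with gamma 2 is bounded above by cross-entropy", {
  set.seed(22)
  for (rep in 1:10) {
    probs <- randProbRows(15, 4)
    y <- sample(4L, 15L, replace = TRUE)
    expect_lte(focalLossMulticlass(probs, y, gamma = 2),
               focalLossMulticlass(probs, y, gamma = 0))
  }
})

test_that("multi-label focal loss reproduces hand-computed values", {
  # perfect predictions -> 0
  Y <- rbind(c(1, 0), c(0, 1))
  P <- rbind(c(1, 0), c(0, 1))
  expect_equal(focalLossMultilabel(P, Y, alphaVec = c(0.5, 0.5)), 0)
  # one sample, one class, label 1, p = 0.9, alpha 0.4, gamma 2
  got <- focalLossMultilabel(matrix(0.9), matrix(1), alphaVec = 0.4)
  expect_equal(got, -0.4 * 0.1^2 * log(0.9), tolerance = 1e-12)
  expect_equal(got, 4.2145e-4, tolerance = 1e-4)
})

test_that("flipping labels and complementing probabilities is symmetric", {
  set.seed(23)
  P <- matrix(runif(18), 6, 3)
  Y <- matrix(rbinom(18, 1, 0.5), 6, 3)
  a <- c(0.4, 0.9, 0.2)
  expect_equal(focalLossMultilabel(P, Y, a),
               focalLossMultilabel(1 - P, 1 - Y, a), tolerance = 1e-12)
})

test_that("both losses match scalar-loop oracles on 100 random draws", {
  set.seed(24)
  worst <- 0
  for (rep in 1:50) {
    m <- sample(2:12, 1)
    n <- sample(2:6, 1)
    probs <- randProbRows(m, n)
    y <- sample(n, m, replace = TRUE)
    a <- runif(1, 0.2, 2)
    g <- sample(c(0, 1, 2, 3), 1)
    worst <- max(worst, abs(focalLossMulticlass(probs, y, a, g) -
                              bruteFocalMulticlass(probs, y, a, g)))
  }
  for (rep in 1:50) {
    m <- sample(2:12, 1)
    n <- sample(2:6, 1)
    P <- matrix(runif(m * n), m, n)
    Y <- matrix(rbinom(m * n, 1, 0.5), m, n)
    av <- runif(n, 0.1, 1)
    g <- sample(c(0, 1, 2), 1)
    worst <- max(worst, abs(focalLossMultilabel(P, Y, av, g) -
                              bruteFocalMultilabel(P, Y, av, g)))
  }
  expect_lt(worst, 1e-6)
})

test_that("losses are nonnegative and decrease as the true probability rises", {
  ps <- seq(0.05, 0.95, by = 0.1)
  lm <- vapply(ps, function(p)
    focalLossMulticlass(matrix(c(p, 1 - p), 1), 1L), 0)
  expect_true(all(lm >= 0))
  expect_true(all(diff(lm) < 0))
  ll <- vapply(ps, function(p)
    focalLossMultilabel(matrix(p), matrix(1), alphaVec = 0.4), 0)
  expect_true(all(ll >= 0))
  expect_true(all(diff(ll) < 0))
})

test_that("zero probabilities are clamped, never NaN", {
  expect_true(is.finite(focalLossMulticlass(matrix(c(0, 1), 1), 1L)))
  expect_true(is.finite(focalLossMultilabel(matrix(0), matrix(1),
                                            alphaVec = 1)))
})
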