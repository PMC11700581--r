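# Long-short term attention: oracle equivalence with vanilla multi-head
# attention in the w >= P, r = 0 limit, segment masking, the dynamic
# projection, dual normalization, and row-stochastic attention weights.

## brute-force O(P^2) multi-head attention oracle (no windows, no long branch)
bruteMHA <- function(x, Wq, Wk, Wv, Wo, bo, heads, dk) {
  P <- nrow(x)
  Q <- x %*% Wq; K <- x %*% Wk; V <- x %*% Wv
  O <- matrix(0, P, heads * dk)
  for (h in seq_len(heads)) {
    ch <- (h - 1L) * dk + seq_len(dk)
    S <- (Q[, ch, drop = FALSE] %*% t(K[, ch, drop = FALSE])) / sqrt(dk)
    A <- t(apply(S, 1L, function(r) {
      e <- exp(r - max(r)); e / sum(e)
    }))
    O[, ch] <- A %*% V[, ch, drop = FALSE]
  }
  sweep(O %*% Wo, 2L, bo, "+")
}

mkAttnModel <- function(rank, window, seed = 4L) {
  cfg <- tinyConfigNoDrop()
  cfg$lsta$rank <- rank
  cfg$lsta$window <- window
  initLocModel(cfg, classNames = c("x", "y", "z"), seed = seed)
}

test_that("with full window and rank 0 the block equals vanilla MHA", {
  model <- mkAttnModel(rank = 0L, window = 99L)
  p <- model@params
  cfg <- model@config$lsta
  set.seed(8)
  for (P in c(3L, 8L, 16L)) {
    x <- matrix(rnorm(P * 4L), P, 4L)
    got <- lstaForward(x, model)
    want <- bruteMHA(x, p$b1_lsta_Wq, p$b1_lsta_Wk, p$b1_lsta_Wv,
                     p$b1_lsta_Wo, p$b1_lsta_bo, cfg$heads, cfg$d_k)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("attention weights are row-stochastic before dropout", {
  model <- mkAttnModel(rank = 2L, window = 8L)
  set.seed(9)
  x <- matrix(rnorm(8 * 4), 8, 4)
  for (A in lstaAttentionWeights(x, model)) {
    expect_true(all(A >= 0))
    expect_true(all(abs(rowSums(A) - 1) < 1e-5))
    expect_equal(ncol(A), 8L + 2L)  # window short keys + r long keys
  }
})

test_that("segment windows partition the positions as documented", {
  expect_equal(shortTermContext(4L, 2L), list(1:2, 3:4))
  expect_equal(shortTermContext(5L, 2L), list(1:2, 3:4, 5L))
  expect_equal(shortTermContext(3L, 99L), list(1:3))
})

test_that("with rank 0, output rows depend only on their own segment", {
  model <- mkAttnModel(rank = 0L, window = 4L)
  set.seed(10)
  x <- matrix(rnorm(8 * 4), 8, 4)
  y1 <- lstaForward(x, model)
  x2 <- x
  x2[5:8, ] <- rnorm(16)  # perturb the second segment only
  y2 <- lstaForward(x2, model)
  expect_equal(y1[1:4, ], y2[1:4, ], tolerance = 1e-12)
  expect_gt(max(abs(y1[5:8, ] - y2[5:8, ])), 1e-4)
})

test_that("dynamic projection: zero scores give column means, P=1 is exact", {
  set.seed(11)
  K <- matrix(rnorm(12), 6, 2)
  V <- matrix(rnorm(12), 6, 2)
  pj <- dynamicProjection(K, V, matrix(0, 2, 3))  # uniform weights
  expect_equal(pj$Kbar, matrix(colMeans(K), 3, 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_true(all(abs(colSums(pj$weights) - 1) < 1e-12))

  K1 <- matrix(rnorm(2), 1, 2)
  pj1 <- dynamicProjection(K1, K1, matrix(rnorm(8), 2, 4))
  expect_equal(pj1$Kbar, matrix(rep(K1, each = 4), 4, 2), tolerance = 1e-12)
})

test_that("projected key count adds r long keys per query", {
  model <- mkAttnModel(rank = 2L, window = 8L)
  A <- lstaAttentionWeights(matrix(rnorm(32), 8, 4), model)[[1L]]
  expect_equal(ncol(A), model@config$lsta$window + model@config$lsta$rank)
})

test_that("layer normalization is invariant to branch rescaling", {
  set.seed(12)
  x <- matrix(rnorm(20), 5, 4)
  g <- runif(4, 0.5, 2)
  b <- rnorm(4)
  n1 <- RNALocNet:::.layerNormForward(x, g, b)$out
  n2 <- RNALocNet:::.layerNormForward(10 * x, g, b)$out
  expect_equal(n1, n2, tolerance = 1e-3)  # exact up to the eps regularizer
  ## zero-variance rows degrade gracefully to the bias
  z <- matrix(2, 3, 4)
  nz <- RNALocNet:::.layerNormForward(z, g, b)$out
  expect_equal(nz, matrix(b, 3, 4, byrow = TRUE), tolerance = 1e-6)
})

test_that("a single position with rank 0 reduces to its value projection", {
  model <- mkAttnModel(rank = 0L, window = 1L)
  p <- model@params
  x <- matrix(rnorm(4), 1, 4)
  got <- lstaForward(x, model)
  want <- sweep((x %*% p$b1_lsta_Wv) %*% p$b1_lsta_Wo, 2L, p$b1_lsta_bo, "+")
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("evaluation-mode forward is deterministic", {
  model <- mkAttnModel(rank = 2L, window = 8L)
  x <- matrix(rnorm(32), 8, 4)
  expect_identical(lstaForward(x, model), lstaForward(x, model))
})
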