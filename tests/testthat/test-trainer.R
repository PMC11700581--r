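# Trainer: stratified folds, the optimization loop, cross-validation and
# grid search, all on the scaled-down architecture.

test_that("stratified folds balance sizes and per-class counts", {
  labs <- factor(rep(c("a", "b", "c", "d", "e"),
                     times = c(314, 159, 276, 59, 34)))
  fold <- stratifiedFolds(labs, k = 5L, seed = 1L)
  expect_equal(sort(as.vector(table(fold)), decreasing = TRUE),
               c(169L, 169L, 168L, 168L, 168L))  # 842 = 5*168 + 2
  perClass <- table(labs, fold)
  expect_true(all(apply(perClass, 1L, function(r) max(r) - min(r)) <= 1L))
})

test_that("ten members of one class split two per fold; seeds reproduce", {
  labs <- factor(rep("only", 10L))
  fold <- stratifiedFolds(labs, k = 5L, seed = 2L, warnSmall = FALSE)
  expect_equal(as.vector(table(fold)), rep(2L, 5L))
  labs2 <- factor(sample(c("a", "b"), 30, TRUE))
  expect_identical(stratifiedFolds(labs2, 5L, seed = 7L),
                   stratifiedFolds(labs2, 5L, seed = 7L))
  expect_warning(stratifiedFolds(factor(c("a", rep("b", 9))), k = 5L),
                 "fewer than")
  expect_error(stratifiedFolds(factor("a"), k = 5L), "between")
})

test_that("training reduces the loss on a separable two-class problem", {
  ds <- tinyDataset()
  cfg <- tinyConfigNoDrop(train = list(lr = 5e-3, batch_size = 8L,
                                       epochs = 5L, seed = 1L))
  m <- trainLocModel(ds, config = cfg)
  h <- trainHistory(m)
  expect_equal(nrow(h), 5L)
  expect_lt(h$train_loss[5L], h$train_loss[1L])
})

test_that("zero learning rate leaves the parameters unchanged", {
  ds <- tinyDataset(n = 16L)
  cfg <- tinyConfigNoDrop(train = list(lr = 0, batch_size = 8L,
                                       epochs = 2L, seed = 1L))
  m <- trainLocModel(ds, config = cfg)
  init <- withr::with_seed(1L, NULL)
  m0 <- initLocModel(cfg, classNames(ds), "single", seed = cfg$train$seed)
  expect_equal(m@params, m0@params, tolerance = 1e-12)
})

test_that("the same seed reproduces the training history exactly", {
  ds <- tinyDataset(n = 24L)
  cfg <- tinyConfig(train = list(lr = 5e-3, batch_size = 8L, epochs = 3L,
                                 seed = 9L))
  fold <- stratifiedFolds(labels(ds), k = 4L, seed = 1L)
  m1 <- trainLocModel(ds[fold != 1], ds[fold == 1], config = cfg)
  m2 <- trainLocModel(ds[fold != 1], ds[fold == 1], config = cfg)
  expect_identical(trainHistory(m1), trainHistory(m2))
  expect_identical(m1@params, m2@params)
})

test_that("the best-validation-maF1 checkpoint is reproducible at reload", {
  ds <- tinyDataset(n = 32L)
  fold <- stratifiedFolds(labels(ds), k = 4L, seed = 2L)
  cfg <- tinyConfig(train = list(lr = 5e-3, batch_size = 8L, epochs = 4L,
                                 seed = 3L))
  m <- trainLocModel(ds[fold != 1], ds[fold == 1], config = cfg)
  ev <- RNALocNet:::.evalOn(
    RNALocNet:::.encodeInput(ds[fold == 1]),
    as.integer(labels(ds[fold == 1])), m@params, cfg, "single")
  h <- trainHistory(m)
  expect_equal(ev$maF1, max(h$valid_maF1), tolerance = 1e-12)
})

test_that("cross-validation returns k reports and a mean/sd summary", {
  ds <- tinyDataset(n = 40L)
  cfg <- tinyConfig(train = list(lr = 5e-3, batch_size = 8L, epochs = 2L,
                                 seed = 1L))
  cv <- crossValidate(ds, cfg, k = 3L, seed = 1L)
  expect_length(cv$reports, 3L)
  expect_true(all(c("acc", "macro_f1") %in% cv$summary$metric))
  expect_true(all(cv$summary$sd >= 0))
  expect_output(print(cv), "3-fold")
})

test_that("grid search evaluates the grid in order and picks the best", {
  ds <- tinyDataset(n = 24L)
  cfg <- tinyConfigNoDrop(train = list(lr = 5e-3, batch_size = 8L,
                                       epochs = 2L, seed = 1L))
  ## 1-point grid returns that configuration
  gs1 <- gridSearch(ds, grid = list(`train.batch_size` = list(8L)),
                    config = cfg, k = 2L, seed = 1L)
  expect_equal(gs1$best$train$batch_size, 8L)
  expect_equal(nrow(gs1$leaderboard), 1L)
  ## sabotaged configuration (lr 0) loses against the trainable one
  gs2 <- gridSearch(ds, grid = list(`train.lr` = list(0, 5e-3)),
                    config = cfg, k = 2L, seed = 1L)
  expect_equal(gs2$best$train$lr, 5e-3)
  expect_equal(nrow(gs2$leaderboard), 2L)
  expect_error(gridSearch(ds, grid = list(), config = cfg), "nonempty")
})

test_that("the published search space has the documented axes", {
  g <- defaultGridSpec()
  expect_equal(unlist(g$`train.batch_size`), c(128L, 256L, 512L))
  expect_length(g$`cm.kernel_sizes`, choose(5L, 2L))
  expect_true(list(c(3L, 5L)) %in% g$`cm.kernel_sizes`)
  expect_equal(unlist(g$`lsta.heads`), c(2L, 4L, 6L, 8L))
  expect_equal(g$`cm.pool_targets`[[2L]], c(512L, 256L, 128L))
})

test_that("a constant predictor scores at the majority prevalence", {
  ## degenerate check of the evaluation path: scores that always rank class
  ## 1 first yield accuracy equal to class 1 prevalence
  y <- c(rep(1L, 7), rep(2L, 3))
  s <- matrix(rep(c(0.9, 0.1), each = 10), 10, 2)
  rep <- computeMetrics(s, y)
  expect_equal(rep$acc, 0.7)
})
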