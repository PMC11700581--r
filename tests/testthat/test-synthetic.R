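# Synthetic dataset generator: planting guarantees, reproducibility, and
# the length distribution.

test_that("planting probability 1 guarantees the class motif as substring", {
  spec <- syntheticSpec(n = rep(5L, 5L), plantProb = 1, tailProb = 0,
                        lengthRange = c(100L, 300L), seed = 31L)
  ds <- generateLocDataset(spec)
  seqs <- as.character(sequences(ds))
  labs <- as.character(labels(ds))
  for (ci in seq_along(spec$classes)) {
    for (s in seqs[labs == spec$classes[ci]])
      expect_true(grepl(spec$motifs[ci], s, fixed = TRUE))
  }
})

test_that("observed planting fraction is within 3 sd of the target", {
  spec <- syntheticSpec(classes = c("X", "Y"), n = c(500L, 500L),
                        plantProb = 0.3, tailProb = 0,
                        lengthRange = c(60L, 120L),
                        motifs = c("CTCAGCCTCCC", "GGACAAGGAGGACCA"),
                        seed = 32L)
  ds <- generateLocDataset(spec)
  hits <- mapply(function(s, cl) {
    grepl(spec$motifs[match(cl, spec$classes)], s, fixed = TRUE)
  }, as.character(sequences(ds)), as.character(labels(ds)))
  phat <- mean(hits)
  ## background hits can only push the fraction up; allow the binomial band
  sd3 <- 3 * sqrt(0.3 * 0.7 / 1000)
  expect_gt(phat, 0.3 - sd3)
  expect_lt(phat, 0.3 + sd3 + 0.02)
})

test_that("the same seed reproduces the FASTA byte-for-byte", {
  spec <- learnableSyntheticSpec(nPerClass = 5L, seed = 33L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateLocDataset(spec, outDir = d1)
  generateLocDataset(spec, outDir = d2)
  expect_identical(readLines(file.path(d1, "sequences.fasta")),
                   readLines(file.path(d2, "sequences.fasta")))
  expect_identical(readLines(file.path(d1, "labels.tsv")),
                   readLines(file.path(d2, "labels.tsv")))
  ## a different seed changes the data
  spec2 <- learnableSyntheticSpec(nPerClass = 5L, seed = 34L)
  d3 <- withr::local_tempdir()
  generateLocDataset(spec2, outDir = d3)
  expect_false(identical(readLines(file.path(d1, "sequences.fasta")),
                         readLines(file.path(d3, "sequences.fasta"))))
})

test_that("generated lengths follow the specified distribution (KS)", {
  spec <- syntheticSpec(n = rep(400L, 5L), tailProb = 0,
                        lengthRange = c(200L, 3000L), plantProb = 0,
                        seed = 35L)
  ds <- generateLocDataset(spec)
  L <- Biostrings::width(sequences(ds))
  expect_true(all(L >= 200L & L <= 3000L))
  ## integer lengths are floor(U) for U ~ Unif(200, 3001); adding U(0,1)
  ## jitter recovers the continuous uniform exactly, so KS applies cleanly
  set.seed(1)
  jit <- L + runif(length(L))
  ks <- stats::ks.test(jit, "punif", 200, 3001)
  expect_gt(ks$p.value, 0.01)
})

test_that("long-tail components produce lengths beyond the core range", {
  spec <- syntheticSpec(n = c(200L, 5L, 5L, 5L, 200L), plantProb = 0,
                        seed = 36L)
  ds <- generateLocDataset(spec)
  L <- Biostrings::width(sequences(ds))
  labs <- as.character(labels(ds))
  expect_gt(max(L[labs %in% c("Nucleus", "Ribosome")]), 3000L)
  expect_true(all(L[!labs %in% c("Nucleus", "Ribosome")] <= 3000L))
  expect_true(all(L <= 12000L))
})

test_that("planted motif coordinates are recorded and correct", {
  spec <- learnableSyntheticSpec(nPerClass = 4L, lengthRange = c(80L, 160L),
                                 plantProb = 1, seed = 37L)
  ds <- generateLocDataset(spec)
  pl <- S4Vectors::metadata(sequences(ds))$planted
  expect_equal(nrow(pl), length(ds))
  for (i in seq_len(nrow(pl))) {
    s <- as.character(sequences(ds)[[pl$id[i]]])
    cl <- as.character(labels(ds))[match(pl$id[i], names(sequences(ds)))]
    motif <- spec$motifs[match(cl, spec$classes)]
    expect_identical(substr(s, pl$start[i], pl$end[i]), motif)
  }
})

test_that("a Markov background changes composition but stays reproducible", {
  tm <- matrix(0.25, 4, 4)
  tm[1, ] <- c(0.7, 0.1, 0.1, 0.1)  # A-rich runs
  spec <- syntheticSpec(classes = c("X", "Y"), n = c(20L, 20L),
                        lengthRange = c(200L, 400L), tailProb = 0,
                        plantProb = 0, motifs = c("AAAA", "CCCC"),
                        background = tm, seed = 38L)
  ds1 <- generateLocDataset(spec)
  ds2 <- generateLocDataset(spec)
  expect_identical(as.character(sequences(ds1)),
                   as.character(sequences(ds2)))
  comp <- Biostrings::alphabetFrequency(sequences(ds1), baseOnly = TRUE)
  expect_gt(sum(comp[, "A"]), sum(comp[, "C"]))
})

test_that("multi-label generation respects priors and the re-draw contract", {
  ds <- generateMultilabelLocDataset(classes = c("u", "v"), n = 400L,
                                     priors = c(0.5, 0.5),
                                     motifs = c("CTCAGCCTCCC",
                                                "GGACAAGGAGGACCA"),
                                     plantProb = 1,
                                     lengthRange = c(60L, 120L), seed = 39L)
  Y <- labels(ds)
  expect_true(all(rowSums(Y) >= 1L))
  ## independent (0.5, 0.5) priors, all-zero redrawn: P(both) = 1/3
  expect_equal(mean(rowSums(Y) == 2L), 1 / 3,
               tolerance = 3 * sqrt(2 / 9 / 400) / (1 / 3))
  ## motifs planted for active labels
  hit <- grepl("CTCAGCCTCCC", as.character(sequences(ds))[Y[, "u"] == 1],
               fixed = TRUE)
  expect_true(all(hit))
  ## prior 1 puts the label on every sequence
  ds2 <- generateMultilabelLocDataset(classes = c("u", "v"), n = 30L,
                                      priors = c(1, 0.2),
                                      lengthRange = c(60L, 120L), seed = 40L)
  expect_true(all(labels(ds2)[, "u"] == 1L))
})
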