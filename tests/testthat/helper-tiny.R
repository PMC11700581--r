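# Shared fixtures: a scaled-down architecture for functional tests (the
# full-size network is exercised in the shape-contract and acceptance
# tests), plus small random dataset builders. Everything is generated in
# code, seeded.

tinyConfig <- function(...) {
  cfg <- locNetConfig(
    cm = list(kernel_sizes = c(2L, 3L), stage_filters = c(6L, 6L, 4L),
              pool_targets = c(24L, 12L, 8L), dropout = 0.2),
    lsta = list(heads = 2L, window = 8L, rank = 2L, d_k = 2L, dropout = 0.2),
    bilstm = list(hidden = 2L, dropout = 0.2),
    textcnn = list(kernel_sizes = c(1L, 2L, 3L), filters = 4L,
                   dropout = 0.05),
    train = list(lr = 5e-3, batch_size = 8L, epochs = 4L, seed = 1L)
  )
  over <- list(...)
  if (length(over)) cfg <- RNALocNet:::.deepMerge(cfg, over)
  RNALocNet:::.validateLocNetConfig(cfg)
  cfg
}

## deterministic-path tiny config: all dropout off
tinyConfigNoDrop <- function(...) {
  cfg <- tinyConfig(...)
  cfg$cm$dropout <- 0
  cfg$lsta$dropout <- 0
  cfg$bilstm$dropout <- 0
  cfg$textcnn$dropout <- 0
  cfg
}

randomSeqs <- function(n, lmin = 20L, lmax = 60L, seed = 1L) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      L <- lmin + sample.int(lmax - lmin + 1L, 1L) - 1L
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
  })
}

tinyDataset <- function(n = 40L, classes = c("A_class", "B_class"),
                        seed = 3L) {
  ## two classes separated by a strong planted motif in class B
  withr::with_seed(seed, {
    seqs <- randomSeqs(n, 30L, 60L, seed = seed + 1L)
    lab <- rep(classes, length.out = n)
    for (i in which(lab == classes[2L])) {
      s <- sample.int(nchar(seqs[i]) - 8L, 1L)
      substr(seqs[i], s, s + 7L) <- "GGGGGGGG"
    }
    names(seqs) <- sprintf("s%03d", seq_len(n))
    LocDataset(seqs, lab, classNames = classes)
  })
}

## parameters jittered away from zero-bias ReLU kinks, for gradient checks
jitteredParams <- function(cfg, nClasses = 3L, seed = 42L) {
  p <- withr::with_seed(seed, RNALocNet:::.initLocParams(cfg, nClasses))
  withr::with_seed(seed + 1L,
    lapply(p, function(x) x + rnorm(length(x), sd = 0.05)))
}
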