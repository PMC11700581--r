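# Sequence IO and per-nucleotide feature encoding.

test_that("sanitizeSequence canonicalizes case, RNA letters and ambiguity", {
  expect_equal(sanitizeSequence("AUGC"), "ATGC")
  expect_equal(sanitizeSequence("acgtn"), "ACGTN")
  expect_equal(sanitizeSequence("AXT"), "ANT")
  expect_equal(sanitizeSequence("uuu"), "TTT")
  expect_equal(nchar(sanitizeSequence("acgu-ryx")), 8L)
  expect_error(sanitizeSequence(""), "non-empty")
})

test_that("encodeSequence produces the documented L x 8 channels", {
  m <- encodeSequence("GACTN")
  expect_equal(dim(m), c(5L, 8L))
  expect_equal(colnames(m), c("onehot_A", "onehot_T", "onehot_C", "onehot_G",
                              "EIIP", "NCP_R", "NCP_F", "NCP_H"))
  expect_equal(unname(m[1L, ]), c(0, 0, 0, 1, 0.0806, 1, 0, 0))  # G
  expect_equal(unname(m[2L, ]), c(1, 0, 0, 0, 0.1260, 1, 1, 1))  # A
  expect_equal(unname(m[3L, ]), c(0, 0, 1, 0, 0.1340, 0, 1, 0))  # C
  expect_equal(unname(m[4L, ]), c(0, 1, 0, 0, 0.1335, 0, 0, 1))  # T
  expect_equal(unname(m[5L, ]), rep(0, 8))                       # N
})

test_that("encoding invariants hold on random sequences", {
  for (seed in 1:5) {
    s <- randomSeqs(1L, 10L, 50L, seed = seed)
    m <- encodeSequence(s)
    expect_equal(nrow(m), nchar(s))
    expect_true(all(rowSums(m[, 1:4]) == 1))          # one-hot sums to 1
    # NCP sub-vector sums: A -> 3, C/G/T -> 1
    ncp <- rowSums(m[, 6:8])
    expect_true(all(ncp[m[, "onehot_A"] == 1] == 3))
    expect_true(all(ncp[m[, "onehot_A"] == 0] == 1))
    expect_true(all(m[, "EIIP"] %in% c(0.1260, 0.1335, 0.1340, 0.0806, 0)))
  }
  # determinism / totality
  expect_identical(encodeSequence("ACGTN"), encodeSequence("ACGTN"))
})

test_that("sequences shorter than the minimum length are rejected", {
  expect_error(encodeSequence("ACG"), "minimum")
  expect_silent(encodeSequence("ACGTA"))
})

test_that("FASTA round-trip preserves ids and residues byte-for-byte", {
  seqs <- randomSeqs(5L, 20L, 40L, seed = 9L)
  names(seqs) <- paste0("tx", 1:5)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeFastaSequences(seqs, fa)
  back <- readFastaSequences(fa)
  expect_identical(names(back), names(seqs))
  expect_identical(unname(as.character(back)), unname(seqs))
})

test_that("FASTA reading sanitizes, trims headers and rejects duplicates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1 some description", "acgu", "acgu",
               ">seq2", "ACGTNXA"), fa)
  s <- readFastaSequences(fa)
  expect_identical(names(s), c("seq1", "seq2"))
  expect_identical(as.character(s[["seq1"]]), "ACGTACGT")
  expect_identical(as.character(s[["seq2"]]), "ACGTNNA")

  writeLines(c(">dup", "ACGT", ">dup", "TTTT"), fa)
  expect_error(readFastaSequences(fa), "duplicate.*dup")
  writeLines(character(), fa)
  expect_error(readFastaSequences(fa))
  expect_error(readFastaSequences("no/such/file.fa"), "not found")
})

test_that("single-label tables validate against the fixed vocabulary", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel", "seq1\tNucleus", "seq2\tRibosome"), tsv)
  labs <- readLabelTable(tsv, "single")
  expect_identical(unname(as.character(labs)), c("Nucleus", "Ribosome"))
  expect_identical(levels(labs), lncCompartments())

  writeLines(c("id\tlabel", "seq1\tMitochondrion"), tsv)
  expect_error(readLabelTable(tsv, "single"), "Mitochondrion")
})

test_that("multi-label tables parse binary vectors and reject all-zero rows", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabels", "seq1\t1,0,0,1,0,0", "seq2\t0,1,0,0,0,0"), tsv)
  m <- readLabelTable(tsv, "multi")
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(unname(m["seq1", ]), c(1L, 0L, 0L, 1L, 0L, 0L))
  expect_identical(colnames(m), mrnaCompartments())

  writeLines(c("id\tlabels", "seq1\t0,0,0,0,0,0"), tsv)
  expect_error(readLabelTable(tsv, "multi"), "all-zero")
})

test_that("label/FASTA id mismatches are hard errors", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel", "seqX\tNucleus"), tsv)
  expect_error(readLabelTable(tsv, "single", ids = c("seq1")), "do not match")
})

test_that("LocDataset validates, subsets and prints", {
  d <- tinyDataset()
  expect_s4_class(d, "LocDataset")
  expect_equal(length(d), 40L)
  expect_identical(labelMode(d), "single")
  sub <- d[1:5]
  expect_equal(length(sub), 5L)
  expect_identical(as.character(labels(sub)),
                   as.character(labels(d))[1:5])
  expect_output(show(d), "LocDataset with 40")
  expect_error(LocDataset(c(a = "ACGTACGT", a = "ACGTACGT"),
                          c("Nucleus", "Cytosol")),
               "duplicate")
})

test_that("readLocDataset joins FASTA and labels, optionally deduplicating", {
  dir <- withr::local_tempdir()
  seqs <- c(s1 = "ACGTACGTGG", s2 = "TTGGCCAAGG", s3 = "ACGTACGTGG")
  writeFastaSequences(seqs, file.path(dir, "x.fa"))
  writeLabelTable(factor(c(s1 = "Nucleus", s2 = "Cytosol", s3 = "Nucleus"),
                         levels = lncCompartments()),
                  file.path(dir, "y.tsv"))
  ds <- readLocDataset(file.path(dir, "x.fa"), file.path(dir, "y.tsv"))
  expect_equal(length(ds), 3L)
  ds2 <- readLocDataset(file.path(dir, "x.fa"), file.path(dir, "y.tsv"),
                        dedupe = TRUE)
  expect_equal(length(ds2), 2L)
})
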