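## Per-nucleotide feature tables.
##
## EIIP: electron-ion interaction pseudopotential of each base.
## NCP: chemical-property triple (ring structure R, functional group F,
## hydrogen bonding H). Ambiguous bases (N) carry all-zero rows so that
## downstream convolutions remain well-defined without inventing values.
.EIIP <- c(A = 0.1260, T = 0.1335, C = 0.1340, G = 0.0806, N = 0)

.NCP <- rbind(A = c(1, 1, 1), C = c(0, 1, 0), G = c(1, 0, 0),
              T = c(0, 0, 1), N = c(0, 0, 0))

.ONEHOT <- rbind(A = c(1, 0, 0, 0), T = c(0, 1, 0, 0), C = c(0, 0, 1, 0),
                 G = c(0, 0, 0, 1), N = c(0, 0, 0, 0))

.ENC_CHANNELS <- c("onehot_A", "onehot_T", "onehot_C", "onehot_G",
                   "EIIP", "NCP_R", "NCP_F", "NCP_H")

## Single per-base encoding table in the fixed channel order; rows A,T,C,G,N.
.ENC_TABLE <- local({
  b <- c("A", "T", "C", "G", "N")
  m <- cbind(.ONEHOT[b, ], .EIIP[b], .NCP[b, ])
  dimnames(m) <- list(b, .ENC_CHANNELS)
  m
})

#' Canonicalize a raw nucleotide string
#'
#' Uppercases, maps U to T (RNA input), and maps every character outside
#' A/C/G/T to N. The result has the same length as the input.
#'
#' @param raw A single non-empty character string.
#' @return Canonical residue string over \{A,C,G,T,N\}.
#' @examples
#' sanitizeSequence("augcx")  # "ATGCN"
#' @export
sanitizeSequence <- function(raw) {
  .assert(is.character(raw) && length(raw) == 1L && nzchar(raw),
          "raw must be a single non-empty string")
  s <- chartr("u", "t", tolower(raw))
  s <- toupper(s)
  gsub("[^ACGT]", "N", s)
}

#' Read (and sanitize) sequences from a FASTA file
#'
#' Ids are taken from the headers up to the first whitespace; record order is
#' preserved; residues are canonicalized with \code{\link{sanitizeSequence}}.
#' Duplicate ids are a hard error.
#'
#' @param path Path to a FASTA file.
#' @return A named \linkS4class{DNAStringSet}.
#' @export
readFastaSequences <- function(path) {
  .assert(file.exists(path), "FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  .assert(length(set) > 0L, "FASTA file is empty: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  .assert(all(nzchar(ids)), "FASTA contains an empty header")
  dup <- ids[duplicated(ids)]
  .assert(length(dup) == 0L, "duplicate FASTA id: %s", dup[1L])
  out <- Biostrings::DNAStringSet(vapply(as.character(set), sanitizeSequence,
                                         "", USE.NAMES = FALSE))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A named \linkS4class{DNAStringSet} or named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
writeFastaSequences <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Encode a sequence as an L x 8 feature matrix
#'
#' Each position becomes an 8-vector in the fixed channel order
#' \code{onehot_A, onehot_T, onehot_C, onehot_G, EIIP, NCP_R, NCP_F, NCP_H}.
#' Ambiguous residues (N) encode as all-zero rows.
#'
#' @param seq A character string, \code{DNAString}, or single-element
#'   \code{DNAStringSet}; sanitized if needed.
#' @param minLength Minimum accepted length (default 5, the widest encoder
#'   kernel); shorter sequences are rejected.
#' @return An L x 8 numeric matrix with channel column names.
#' @examples
#' encodeSequence("GA")  # rows: G then A
#' @export
encodeSequence <- function(seq, minLength = 5L) {
  if (is(seq, "DNAStringSet")) {
    .assert(length(seq) == 1L, "encodeSequence takes a single sequence")
    seq <- as.character(seq[[1L]])
  } else if (!is.character(seq)) seq <- as.character(seq)
  seq <- sanitizeSequence(seq)
  L <- nchar(seq)
  .assert(L >= minLength,
          "sequence length %d below the minimum accepted length %d", L,
          minLength)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- .ENC_TABLE[chars, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Encode every sequence of a set
#'
#' @param seqs A named \linkS4class{DNAStringSet} or character vector.
#' @param minLength Passed to \code{\link{encodeSequence}}.
#' @return A named list of L x 8 matrices.
#' @export
encodeSequences <- function(seqs, minLength = 5L) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  lapply(seqs, encodeSequence, minLength = minLength)
}

#' Read a label table
#'
#' Single-label mode expects a two-column TSV (id, class) with a header;
#' multi-label mode expects id plus a comma-separated binary vector over the
#' class vocabulary. The vocabulary is fixed by \code{classes}, never
#' inferred from the file.
#'
#' @param path Path to the TSV.
#' @param mode \code{"single"} or \code{"multi"}.
#' @param classes Class vocabulary (defaults per mode).
#' @param ids Optional character vector of expected sequence ids (e.g. from a
#'   companion FASTA); a mismatch is an error and rows are reordered to match.
#' @return Factor (single) or binary matrix (multi), named/rownamed by id.
#' @export
readLabelTable <- function(path, mode = c("single", "multi"), classes = NULL,
                           ids = NULL) {
  mode <- match.arg(mode)
  .assert(file.exists(path), "label file not found: %s", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  .assert(ncol(tab) >= 2L, "label table needs two tab-separated columns")
  rid <- tab[[1L]]
  .assert(!anyDuplicated(rid), "duplicate id in label table: %s",
          rid[duplicated(rid)][1L])
  if (mode == "single") {
    classes <- classes %||% lncCompartments()
    lab <- tab[[2L]]
    bad <- setdiff(unique(lab), classes)
    .assert(length(bad) == 0L, "unknown class name in label table: %s",
            bad[1L])
    out <- factor(lab, levels = classes)
    names(out) <- rid
  } else {
    classes <- classes %||% mrnaCompartments()
    rows <- strsplit(tab[[2L]], ",", fixed = TRUE)
    .assert(all(lengths(rows) == length(classes)),
            "multi-label rows must have %d comma-separated entries",
            length(classes))
    out <- do.call(rbind, lapply(rows, as.integer))
    .assert(all(out %in% c(0L, 1L)), "multi-label entries must be 0 or 1")
    .assert(all(rowSums(out) >= 1L), "all-zero multi-label row for id %s",
            rid[rowSums(out) < 1L][1L])
    dimnames(out) <- list(rid, classes)
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, rid)
    extra <- setdiff(rid, ids)
    .assert(length(miss) == 0L && length(extra) == 0L,
            "label table ids do not match sequence ids (e.g. %s)",
            c(miss, extra)[1L])
    out <- if (mode == "single") out[ids] else out[ids, , drop = FALSE]
  }
  out
}

#' Write a label table (inverse of \code{readLabelTable})
#'
#' @param labs Factor (named) or binary matrix (rownamed).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeLabelTable <- function(labs, path) {
  if (is.matrix(labs)) {
    df <- data.frame(id = rownames(labs),
                     labels = apply(labs, 1L, paste, collapse = ","))
  } else {
    df <- data.frame(id = names(labs), label = as.character(labs))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA + label TSV pair into a LocDataset
#'
#' @param fasta,labels File paths.
#' @param mode,classes Passed to \code{\link{readLabelTable}}.
#' @param dedupe Drop exact duplicate sequences (keeping the first)?
#' @return A \linkS4class{LocDataset}.
#' @export
readLocDataset <- function(fasta, labels, mode = c("single", "multi"),
                           classes = NULL, dedupe = FALSE) {
  mode <- match.arg(mode)
  seqs <- readFastaSequences(fasta)
  labs <- readLabelTable(labels, mode = mode, classes = classes,
                         ids = names(seqs))
  if (dedupe) {
    keep <- !duplicated(as.character(seqs))
    seqs <- seqs[keep]
    labs <- if (mode == "single") labs[keep] else labs[keep, , drop = FALSE]
  }
  if (mode == "single")
    LocDataset(stats::setNames(as.character(seqs), names(seqs)), labs,
               classNames = classes %||% lncCompartments())
  else
    LocDataset(stats::setNames(as.character(seqs), names(seqs)), labs,
               classNames = classes %||% mrnaCompartments())
}
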