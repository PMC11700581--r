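## Occlusion attribution: slide a window along the sequence, replace the
## residues under it with N (the all-zero encoding, consistent with the
## ambiguity policy), and record how much the target-class probability
## drops. A position's score is the mean drop over the windows covering it.

#' Occlusion attribution for one sequence
#'
#' @param model A \linkS4class{LocModel}, or a function taking a character
#'   sequence and returning the target-class probability (useful for
#'   surrogate models in sanity checks).
#' @param seq A character string / DNAString (sanitized internally).
#' @param targetClass Class whose probability is tracked (model mode);
#'   defaults to the model's predicted class for the intact sequence.
#' @param window Occlusion window width (nt).
#' @param stride Step between window starts; a final window is added so the
#'   sequence end is always covered.
#' @param id Sequence id for the track.
#' @param batchSize Occluded variants evaluated per forward batch.
#' @return An \linkS4class{AttributionTrack}.
#' @export
occlusionAttribution <- function(model, seq, targetClass = NULL,
                                 window = 15L, stride = 1L, id = "seq",
                                 batchSize = 64L) {
  if (!is.character(seq)) seq <- as.character(seq)
  seq <- sanitizeSequence(seq)
  L <- nchar(seq)
  .assert(window >= 1L && window <= L,
          "window must be in [1, sequence length]")
  .assert(stride >= 1L, "stride must be >= 1")
  if (is.function(model)) {
    probFun <- function(ss) vapply(ss, model, 0, USE.NAMES = FALSE)
    targetClass <- targetClass %||% "target"
  } else {
    .assert(is(model, "LocModel"), "model must be a LocModel or a function")
    if (is.null(targetClass)) {
      p0 <- predictProbs(model, seq)
      targetClass <- model@classNames[which.max(p0[1L, ])]
    }
    .assert(targetClass %in% model@classNames, "unknown target class: %s",
            targetClass)
    probFun <- function(ss) predictProbs(model, ss,
                                         batchSize = batchSize)[, targetClass]
  }
  baseline <- probFun(seq)
  starts <- seq.int(1L, L - window + 1L, by = stride)
  if (starts[length(starts)] != L - window + 1L)
    starts <- c(starts, L - window + 1L)
  occluded <- vapply(starts, function(s) {
    v <- seq
    substr(v, s, s + window - 1L) <- strrep("N", window)
    v
  }, "")
  drops <- baseline - probFun(occluded)
  scoreSum <- numeric(L)
  cover <- numeric(L)
  for (wi in seq_along(starts)) {
    idx <- starts[wi]:(starts[wi] + window - 1L)
    scoreSum[idx] <- scoreSum[idx] + drops[wi]
    cover[idx] <- cover[idx] + 1
  }
  new("AttributionTrack", id = id, scores = scoreSum / cover,
      window = as.integer(window), stride = as.integer(stride),
      targetClass = targetClass, baseline = unname(baseline))
}

#' Write an attribution track as a two-column TSV (position, score)
#' @param track An \linkS4class{AttributionTrack}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAttributionTSV <- function(track, path) {
  write.table(data.frame(position = seq_along(track@scores),
                         score = track@scores),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Top-scoring attribution windows in BED-like form
#'
#' 0-based half-open intervals of the \code{n} highest-scoring windows
#' (window width = the track's occlusion window), greedily non-overlapping.
#'
#' @param track An \linkS4class{AttributionTrack}.
#' @param n Maximum number of windows.
#' @return Data frame with columns chrom (the id), start, end, score.
#' @export
attributionBed <- function(track, n = 5L) {
  L <- length(track@scores)
  w <- track@window
  starts <- seq_len(L - w + 1L)
  winScore <- vapply(starts,
                     function(s) mean(track@scores[s:(s + w - 1L)]), 0)
  ord <- order(-winScore, starts)
  keep <- integer()
  for (s in ord) {
    if (length(keep) >= n) break
    if (all(abs(starts[s] - starts[keep]) >= w)) keep <- c(keep, s)
  }
  data.frame(chrom = track@id, start = starts[keep] - 1L,
             end = starts[keep] - 1L + w, score = winScore[keep])
}
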