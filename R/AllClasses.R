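#' @import methods
NULL

#' Compartment vocabularies
#'
#' Fixed class vocabularies for the two prediction modes: five lncRNA
#' compartments (single-label) and six mRNA compartments (multi-label).
#'
#' @name compartments
#' @aliases lncCompartments mrnaCompartments
#' @return A character vector of compartment names.
#' @examples
#' lncCompartments()
#' @export
lncCompartments <- function() {
  c("Nucleus", "Exosome", "Cytoplasm", "Cytosol", "Ribosome")
}

#' @rdname compartments
#' @export
mrnaCompartments <- function() {
  c("nucleus", "exosome", "cytosol", "ribosome", "membrane", "ER")
}

#' LocDataset: labeled nucleotide sequences
#'
#' Container pairing a \linkS4class{DNAStringSet} of sanitized sequences
#' (alphabet A/C/G/T/N) with localization labels, either a factor over a
#' fixed compartment vocabulary (single-label mode) or a binary matrix with
#' one column per compartment (multi-label mode).
#'
#' @slot sequences A \linkS4class{DNAStringSet}; names are the sequence ids.
#' @slot labels A factor (single-label) or binary integer matrix
#'   (multi-label) aligned with \code{sequences}.
#' @slot labelMode \code{"single"} or \code{"multi"}.
#' @slot classNames The fixed compartment vocabulary.
#' @exportClass LocDataset
setClass("LocDataset",
  representation(sequences = "ANY", labels = "ANY",
                 labelMode = "character", classNames = "character"))

setValidity("LocDataset", function(object) {
  msg <- character()
  s <- object@sequences
  if (!is(s, "DNAStringSet")) msg <- c(msg, "sequences must be a DNAStringSet")
  ids <- names(s)
  if (is.null(ids) || any(!nzchar(ids))) msg <- c(msg, "all sequences need non-empty ids")
  else if (anyDuplicated(ids)) {
    msg <- c(msg, sprintf("duplicate sequence id: %s", ids[duplicated(ids)][1L]))
  }
  if (!object@labelMode %in% c("single", "multi"))
    msg <- c(msg, "labelMode must be 'single' or 'multi'")
  if (length(object@classNames) < 2L) msg <- c(msg, "need at least 2 classes")
  if (object@labelMode == "single") {
    l <- object@labels
    if (!is.factor(l) || length(l) != length(s))
      msg <- c(msg, "single-label mode needs a factor aligned with sequences")
    else if (!identical(levels(l), object@classNames))
      msg <- c(msg, "label levels must equal classNames")
    else if (anyNA(l)) msg <- c(msg, "labels contain values outside classNames")
  } else {
    l <- object@labels
    if (!is.matrix(l) || nrow(l) != length(s))
      msg <- c(msg, "multi-label mode needs a matrix with one row per sequence")
    else {
      if (!all(l %in% c(0L, 1L))) msg <- c(msg, "multi-label entries must be 0/1")
      if (ncol(l) != length(object@classNames))
        msg <- c(msg, "label matrix needs one column per class")
      if (any(rowSums(l) < 1)) msg <- c(msg, "every sequence needs at least one label")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LocDataset
#'
#' @param sequences A named \linkS4class{DNAStringSet} or named character
#'   vector of nucleotide sequences (sanitized on the way in).
#' @param labels Factor/character vector (single-label) or binary matrix
#'   (multi-label).
#' @param classNames Compartment vocabulary; defaults to
#'   \code{lncCompartments()} for single-label and \code{mrnaCompartments()}
#'   for multi-label input.
#' @return A \linkS4class{LocDataset}.
#' @examples
#' d <- LocDataset(c(a = "ACGTACGT", b = "TTTTCCCC"),
#'                 c("Nucleus", "Cytosol"))
#' d
#' @export
LocDataset <- function(sequences, labels, classNames = NULL) {
  if (is.character(sequences)) {
    ids <- names(sequences)
    sequences <- Biostrings::DNAStringSet(vapply(unname(sequences),
                                                 sanitizeSequence, ""))
    names(sequences) <- ids
  }
  if (is.matrix(labels)) {
    classNames <- classNames %||% colnames(labels) %||% mrnaCompartments()
    storage.mode(labels) <- "integer"
    colnames(labels) <- classNames
    obj <- new("LocDataset", sequences = sequences, labels = labels,
               labelMode = "multi", classNames = classNames)
  } else {
    classNames <- classNames %||% lncCompartments()
    labels <- factor(as.character(labels), levels = classNames)
    obj <- new("LocDataset", sequences = sequences, labels = labels,
               labelMode = "single", classNames = classNames)
  }
  validObject(obj)
  obj
}

#' @rdname LocDataset-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' Accessors for LocDataset
#'
#' @param x,object A \linkS4class{LocDataset}.
#' @return \code{sequences}: the DNAStringSet; \code{labels}: the label
#'   factor or matrix; \code{labelMode}, \code{classNames}: character.
#' @name LocDataset-accessors
#' @aliases sequences labelMode classNames
#' @export
setMethod("sequences", "LocDataset", function(x) x@sequences)

#' @rdname LocDataset-accessors
#' @export
setGeneric("labelMode", function(x) standardGeneric("labelMode"))
#' @rdname LocDataset-accessors
setMethod("labelMode", "LocDataset", function(x) x@labelMode)

#' @rdname LocDataset-accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname LocDataset-accessors
setMethod("classNames", "LocDataset", function(x) x@classNames)

#' @rdname LocDataset-accessors
#' @param ... ignored.
#' @export
setMethod("labels", "LocDataset", function(object, ...) object@labels)

#' @rdname LocDataset-accessors
#' @export
setMethod("length", "LocDataset", function(x) length(x@sequences))

#' Subset a LocDataset
#' @param x A \linkS4class{LocDataset}.
#' @param i Index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "LocDataset", function(x, i, j, ..., drop = FALSE) {
  lab <- if (x@labelMode == "single") x@labels[i, drop = FALSE]
         else x@labels[i, , drop = FALSE]
  new("LocDataset", sequences = x@sequences[i], labels = lab,
      labelMode = x@labelMode, classNames = x@classNames)
})

setMethod("show", "LocDataset", function(object) {
  cat(sprintf("LocDataset with %d sequences (%s-label, %d classes)\n",
              length(object), object@labelMode, length(object@classNames)))
  w <- Biostrings::width(object@sequences)
  cat(sprintf("  lengths: %d-%d nt (median %d)\n",
              min(w), max(w), as.integer(stats::median(w))))
  if (object@labelMode == "single") {
    tab <- table(object@labels)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  } else {
    cs <- colSums(object@labels)
    cat("  label counts:",
        paste(sprintf("%s=%d", names(cs), cs), collapse = ", "), "\n")
  }
})

#' LocModel: a trained localization network
#'
#' Holds the architecture configuration, the learned parameter arrays and the
#' training history of the localization network (convolution/adaptive-pool
#' encoder, long-short term attention + Bi-LSTM towers, TextCNN head).
#'
#' @slot config Full model configuration list (see \code{\link{locNetConfig}}).
#' @slot params Named list of parameter matrices/arrays.
#' @slot classNames Output class vocabulary.
#' @slot labelMode \code{"single"} (softmax) or \code{"multi"} (sigmoid).
#' @slot history Per-epoch training/validation history.
#' @exportClass LocModel
setClass("LocModel",
  representation(config = "list", params = "list", classNames = "character",
                 labelMode = "character", history = "data.frame"))

setMethod("show", "LocModel", function(object) {
  np <- sum(vapply(object@params, length, 0L))
  cat(sprintf("LocModel (%s-label, %d classes: %s)\n", object@labelMode,
              length(object@classNames),
              paste(object@classNames, collapse = ", ")))
  cat(sprintf("  %d parameters; CM kernels %s; interface %dx%d\n",
              np, paste(object@config$cm$kernel_sizes, collapse = "/"),
              object@config$cm$pool_targets[3], object@config$cm$stage_filters[3]))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs (best valid maF1 %.3f)\n",
                max(object@history$epoch),
                suppressWarnings(max(object@history$valid_maF1, na.rm = TRUE))))
})

#' @rdname LocModel-accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' Accessors for LocModel
#' @param x A \linkS4class{LocModel}.
#' @return \code{modelConfig}: the configuration list;
#'   \code{trainHistory}: a data.frame of per-epoch losses and metrics.
#' @name LocModel-accessors
#' @aliases modelConfig trainHistory
#' @export
setMethod("modelConfig", "LocModel", function(x) x@config)

#' @rdname LocModel-accessors
#' @export
setGeneric("trainHistory", function(x) standardGeneric("trainHistory"))
#' @rdname LocModel-accessors
setMethod("trainHistory", "LocModel", function(x) x@history)

#' @rdname LocModel-accessors
#' @export
setMethod("classNames", "LocModel", function(x) x@classNames)
#' @rdname LocModel-accessors
#' @export
setMethod("labelMode", "LocModel", function(x) x@labelMode)

#' AttributionTrack: per-position occlusion attributions
#'
#' @slot id Sequence id.
#' @slot scores Per-position attribution (probability drop), length L.
#' @slot window,stride Occlusion window width and stride (nt).
#' @slot targetClass Class whose probability was tracked.
#' @slot baseline Model probability of the intact sequence.
#' @exportClass AttributionTrack
setClass("AttributionTrack",
  representation(id = "character", scores = "numeric", window = "integer",
                 stride = "integer", targetClass = "character",
                 baseline = "numeric"))

setValidity("AttributionTrack", function(object) {
  if (!all(is.finite(object@scores))) "scores must be finite" else TRUE
})

setMethod("show", "AttributionTrack", function(object) {
  cat(sprintf(
    "AttributionTrack %s (%d nt): target %s, window %d, stride %d\n",
    object@id, length(object@scores), object@targetClass, object@window,
    object@stride))
  cat(sprintf("  baseline p = %.4f; score range [%.4g, %.4g]\n",
              object@baseline, min(object@scores), max(object@scores)))
})

#' @rdname AttributionTrack-class
#' @param x An \linkS4class{AttributionTrack}.
#' @return \code{attributionScores}: numeric vector of per-position scores.
#' @export
setGeneric("attributionScores", function(x) standardGeneric("attributionScores"))
#' @rdname AttributionTrack-class
#' @export
setMethod("attributionScores", "AttributionTrack", function(x) x@scores)
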