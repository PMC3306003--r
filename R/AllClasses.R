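#' @import methods
NULL

#' IndicatorSet: binary indicator channels of a DNA sequence
#'
#' The Voss representation of a DNA sequence: four binary vectors
#' \code{I_A}, \code{I_T}, \code{I_C}, \code{I_G}, one per nucleotide, with
#' a 1 wherever that nucleotide occurs.  Ambiguous bases (anything outside
#' A/C/G/T, normalised to \code{N}) contribute 0 to every channel, so the
#' per-position sum of the four channels is 1 on unambiguous positions and
#' 0 on ambiguous ones.
#'
#' @slot seqId character(1) identifier of the source sequence.
#' @slot channels integer matrix with rows \code{A}, \code{T}, \code{C},
#'   \code{G} and one column per base.
#'
#' @export
setClass("IndicatorSet",
  representation(seqId = "character", channels = "matrix"))

setValidity("IndicatorSet", function(object) {
  ch <- object@channels
  if (!identical(rownames(ch), c("A", "T", "C", "G")))
    return("channels must have rows A, T, C, G")
  if (length(ch) && !all(ch %in% c(0L, 1L)))
    return("channel entries must be 0 or 1")
  if (length(ch) && any(colSums(ch) > 1L))
    return("at most one channel may be 1 at a position")
  TRUE
})

#' ScoreTrack: per-position period-3 score along a sequence
#'
#' Holds one non-negative score per base of a sequence, aligned to sequence
#' coordinates: \code{values[i]} is the score of position
#' \code{offset + i - 1} (1-based).  Tracks produced by
#' \code{\link{scoreSequence}} and \code{\link{dftS3Track}} cover the whole
#' sequence (\code{offset = 1}, one value per base), with zero-filled
#' margins where the analysis window does not fit.
#'
#' @slot seqId character(1) sequence identifier.
#' @slot values numeric vector of non-negative scores.
#' @slot offset integer(1), 1-based position of \code{values[1]}.
#' @slot windowLength integer(1), analysis window (impulse-train or DFT
#'   window length, in bases) used to compute the track.
#' @slot method character(1), provenance label (e.g. \code{"xcorr"},
#'   \code{"xcorr+dwt"}, \code{"dft"}).
#'
#' @export
setClass("ScoreTrack",
  representation(seqId = "character", values = "numeric",
                 offset = "integer", windowLength = "integer",
                 method = "character"),
  prototype(offset = 1L, windowLength = NA_integer_, method = "xcorr"))

setValidity("ScoreTrack", function(object) {
  if (length(object@seqId) != 1L) return("seqId must be length 1")
  if (length(object@values) && min(object@values) < 0)
    return("scores must be non-negative")
  if (length(object@offset) != 1L || is.na(object@offset) ||
      object@offset < 1L)
    return("offset must be a positive integer")
  TRUE
})

#' ConfusionCounts: nucleotide-level confusion matrix
#'
#' @slot TP,TN,FP,FN numeric(1) non-negative counts of true positive,
#'   true negative, false positive and false negative nucleotides.
#'
#' @export
setClass("ConfusionCounts",
  representation(TP = "numeric", TN = "numeric", FP = "numeric",
                 FN = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@TN, object@FP, object@FN)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0))
    return("TP, TN, FP, FN must be single non-negative numbers")
  TRUE
})

#' ThresholdModel: trained score threshold
#'
#' Stores the four training statistics (mean and standard deviation of the
#' period-3 score over exon and intron training positions) and the derived
#' decision threshold
#' \deqn{T = (sd_e \cdot mean_i + sd_i \cdot mean_e) / (sd_e + sd_i),}
#' a standard-deviation-weighted compromise between the two class means.
#'
#' @slot meanExon,sdExon,meanIntron,sdIntron numeric(1) training statistics.
#' @slot threshold numeric(1) the derived threshold T.
#'
#' @export
setClass("ThresholdModel",
  representation(meanExon = "numeric", sdExon = "numeric",
                 meanIntron = "numeric", sdIntron = "numeric",
                 threshold = "numeric"))

#' RocCurve: threshold-swept nucleotide-level ROC
#'
#' @slot thresholds numeric vector, descending; the first entry is an
#'   \code{Inf} sentinel at which nothing is called exonic.
#' @slot tpr,fpr numeric vectors in [0, 1], non-decreasing along the sweep.
#' @slot auc numeric(1), trapezoidal area under the curve.
#'
#' @export
setClass("RocCurve",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric"))

setValidity("RocCurve", function(object) {
  if (length(object@tpr) != length(object@fpr) ||
      length(object@tpr) != length(object@thresholds))
    return("thresholds, tpr, fpr must have equal length")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    return("tpr and fpr must be non-decreasing as the threshold falls")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

setMethod("show", "IndicatorSet", function(object) {
  cat("IndicatorSet for", object@seqId, "(", ncol(object@channels),
      "bases )\n")
  if (ncol(object@channels)) {
    n <- min(ncol(object@channels), 20L)
    for (b in rownames(object@channels))
      cat(sprintf("  I_%s: %s%s\n", b,
                  paste(object@channels[b, seq_len(n)], collapse = ""),
                  if (ncol(object@channels) > n) "..." else ""))
  }
  invisible(object)
})

setMethod("show", "ScoreTrack", function(object) {
  cat("ScoreTrack:", object@seqId, "|", length(object@values),
      "positions | method", object@method, "| window",
      object@windowLength, "\n")
  if (length(object@values))
    cat(sprintf("  score range [%.4g, %.4g], offset %d\n",
                min(object@values), max(object@values), object@offset))
  invisible(object)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g TN=%g FP=%g FN=%g\n",
              object@TP, object@TN, object@FP, object@FN))
  invisible(object)
})

setMethod("show", "ThresholdModel", function(object) {
  cat(sprintf(
    "ThresholdModel: T=%.6g (exon %.6g +/- %.6g, intron %.6g +/- %.6g)\n",
    object@threshold, object@meanExon, object@sdExon, object@meanIntron,
    object@sdIntron))
  invisible(object)
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d thresholds, AUC = %.6f\n",
              length(object@thresholds), object@auc))
  invisible(object)
})

# ---- accessors ----

#' @rdname ScoreTrack-class
#' @param x a \code{ScoreTrack}.
#' @export
trackValues <- function(x) {
  stopifnot(is(x, "ScoreTrack"))
  x@values
}

#' @rdname ScoreTrack-class
#' @export
trackSeqId <- function(x) {
  stopifnot(is(x, "ScoreTrack"))
  x@seqId
}

#' @rdname ScoreTrack-class
#' @export
trackOffset <- function(x) {
  stopifnot(is(x, "ScoreTrack"))
  x@offset
}

#' @rdname IndicatorSet-class
#' @param x an \code{IndicatorSet}.
#' @param base one of "A", "T", "C", "G".
#' @export
indicatorChannel <- function(x, base = c("A", "T", "C", "G")) {
  stopifnot(is(x, "IndicatorSet"))
  base <- match.arg(base)
  as.integer(x@channels[base, ])
}

#' @rdname ConfusionCounts-class
#' @param x a \code{ConfusionCounts}.
#' @export
confusionAsVector <- function(x) {
  stopifnot(is(x, "ConfusionCounts"))
  c(TP = x@TP, TN = x@TN, FP = x@FP, FN = x@FN)
}

#' @rdname ThresholdModel-class
#' @param x a \code{ThresholdModel}.
#' @export
modelThreshold <- function(x) {
  stopifnot(is(x, "ThresholdModel"))
  x@threshold
}

#' @rdname RocCurve-class
#' @param x a \code{RocCurve}.
#' @export
rocAuc <- function(x) {
  stopifnot(is(x, "RocCurve"))
  x@auc
}
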