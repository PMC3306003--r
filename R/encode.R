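#' Encode a DNA sequence as binary indicator channels
#'
#' The Voss mapping: a sequence of length N becomes four binary vectors
#' I_A, I_T, I_C, I_G of length N, where I_X[n] = 1 exactly when the
#' residue at position n is X.  For example, ATCCGATATTC gives
#' I_A = 10000101000.  Positions holding \code{N} (or any ambiguity code,
#' normalised to N on input) are 0 in all four channels.
#'
#' @param x a character string, \code{DNAString} or single-element
#'   \code{DNAStringSet}.
#' @param seqId identifier stored in the result; defaults to the name of
#'   \code{x} when present.
#' @return an \code{\link{IndicatorSet}}.
#' @examples
#' indicatorChannel(encodeIndicators("ATCCGATATTC"), "A")
#' @export
setGeneric("encodeIndicators",
  function(x, seqId = "seq") standardGeneric("encodeIndicators"))

#' @rdname encodeIndicators
setMethod("encodeIndicators", "character", function(x, seqId = "seq") {
  stopifnot(length(x) == 1L)
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  m <- matrix(0L, nrow = 4L, ncol = length(ch),
              dimnames = list(c("A", "T", "C", "G"), NULL))
  for (b in rownames(m)) m[b, ] <- as.integer(ch == b)
  new("IndicatorSet", seqId = seqId, channels = m)
})

#' @rdname encodeIndicators
setMethod("encodeIndicators", "DNAString", function(x, seqId = "seq") {
  encodeIndicators(as.character(x), seqId = seqId)
})

#' @rdname encodeIndicators
setMethod("encodeIndicators", "DNAStringSet", function(x, seqId = NULL) {
  stopifnot(length(x) == 1L)
  if (is.null(seqId))
    seqId <- if (!is.null(names(x))) names(x)[1L] else "seq"
  encodeIndicators(as.character(x[[1L]]), seqId = seqId)
})
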