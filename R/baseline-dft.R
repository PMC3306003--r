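#' Sliding-window DFT spectral-content track (baseline)
#'
#' The classical spectral-content measure for coding-region detection: for
#' each window of length \code{windowLength} (a multiple of 3), the squared
#' magnitude of each indicator channel's DFT coefficient at bin
#' \code{windowLength / 3} (frequency 2*pi/3) is computed and the four
#' channels are summed,
#' \deqn{S[w] = \sum_{X} \left| \sum_{n=0}^{N_w-1} I_X[w+n]\,
#'   e^{-2\pi i n/3} \right|^2.}
#' Scores are assigned to window centres; margins where the window does not
#' fit are zero.
#'
#' Two implementations are provided: a direct per-window evaluation of the
#' single DFT coefficient, and a cumulative-sum sliding update used by
#' default.  They agree to floating-point rounding (the sliding form
#' factors out a unit-magnitude phase).
#'
#' @param x sequence (character, \code{DNAString}, or single-element
#'   \code{DNAStringSet}).
#' @param windowLength window length in bases, divisible by 3; default 351.
#' @param engine \code{"sliding"} (cumulative sums) or \code{"direct"}.
#' @param seqId identifier for the track; defaults to the sequence name.
#' @return a \code{\link{ScoreTrack}} with one value per base.
#' @export
dftS3Track <- function(x, windowLength = 351L,
                       engine = c("sliding", "direct"), seqId = NULL) {
  engine <- match.arg(engine)
  if (is(x, "DNAStringSet")) {
    if (is.null(seqId) && !is.null(names(x))) seqId <- names(x)[1L]
    x <- as.character(x[[1L]])
  } else if (is(x, "DNAString")) {
    x <- as.character(x)
  }
  if (is.null(seqId)) seqId <- "seq"
  if (windowLength %% 3L != 0L)
    stop("windowLength must be divisible by 3")
  N <- nchar(x)
  if (N < windowLength)
    stop("sequence shorter than the DFT window")
  ind <- encodeIndicators(x, seqId = seqId)
  nWin <- N - windowLength + 1L
  S <- numeric(nWin)
  w3 <- exp(-2i * pi * (0:(N - 1L)) / 3)
  for (b in c("A", "T", "C", "G")) {
    I <- as.numeric(indicatorChannel(ind, b))
    if (engine == "sliding") {
      cs <- cumsum(I * w3)
      S <- S + Mod(cs[windowLength:N] -
                     c(0, cs[seq_len(N - windowLength)]))^2
    } else {
      e <- exp(-2i * pi * (0:(windowLength - 1L)) / 3)
      for (w in seq_len(nWin))
        S[w] <- S[w] + Mod(sum(I[w:(w + windowLength - 1L)] * e))^2
    }
  }
  half <- windowLength %/% 2L
  v <- numeric(N)
  v[half + seq_len(nWin)] <- S
  new("ScoreTrack", seqId = seqId, values = v, offset = 1L,
      windowLength = as.integer(windowLength), method = "dft")
}
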