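#' Design the period-3 emphasis FIR bandpass
#'
#' A linear-phase FIR bandpass obtained by windowing the ideal bandpass
#' with a Hamming taper (via \code{\link[signal]{fir1}}), centred on the
#' period-3 frequency 2*pi/3 radians per base.  The defaults are an order-8
#' (9-tap) Hamming design; the half bandwidth is 0.05 cycles/base (an
#' order-8 filter cannot realise a narrow band, so only the centre
#' frequency is critical).
#'
#' @param order filter order (taps - 1); default 8.
#' @param centerFreq centre frequency in radians per base; default 2*pi/3.
#' @param halfBandwidth half bandwidth in cycles per base; default 0.05.
#' @param window taper name; only \code{"hamming"} and \code{"hanning"} are
#'   accepted.
#' @return numeric vector of \code{order + 1} symmetric taps, scaled to
#'   unit gain at the band centre.
#' @examples
#' taps <- designFir()
#' length(taps)  # 9
#' @export
designFir <- function(order = 8L, centerFreq = 2 * pi / 3,
                      halfBandwidth = 0.05,
                      window = c("hamming", "hanning")) {
  window <- match.arg(window)
  if (order < 2L) stop("filter order must be >= 2")
  if (!(centerFreq > 0 && centerFreq < pi))
    stop("centerFreq must lie in (0, pi) radians per base")
  fc <- centerFreq / (2 * pi)            # cycles/base
  lo <- fc - halfBandwidth
  hi <- fc + halfBandwidth
  if (halfBandwidth <= 0 || lo <= 0 || hi >= 0.5)
    stop("band edges must stay inside (0, 0.5) cycles per base")
  win <- switch(window,
    hamming = signal::hamming(order + 1L),
    hanning = signal::hanning(order + 1L))
  # fir1 frequencies are normalised to Nyquist = 1 = 0.5 cycles/base
  as.numeric(signal::fir1(order, c(2 * lo, 2 * hi), type = "pass",
                          window = win))
}

#' Evaluate an FIR magnitude response on a frequency grid
#'
#' @param taps FIR taps.
#' @param omega frequencies in radians per base.
#' @return \code{|H(e^{i omega})|} at each frequency.
#' @export
firResponse <- function(taps, omega) {
  vapply(omega, function(w)
    Mod(sum(taps * exp(-1i * w * (seq_along(taps) - 1)))), 0)
}

#' Apply a linear-phase FIR filter with group-delay compensation
#'
#' Zero-padded convolution whose constant group delay (order/2 samples) is
#' removed, so output index n corresponds to input index n.
#'
#' @param taps odd-length symmetric tap vector.
#' @param x input signal.
#' @return filtered signal, same length as \code{x}.
#' @export
applyFir <- function(taps, x) {
  if (length(x) == 0L) stop("empty input signal")
  if (length(taps) %% 2L == 0L)
    stop("taps must be odd-length (linear phase, integer group delay)")
  d <- (length(taps) - 1L) %/% 2L
  y <- stats::convolve(c(x, numeric(2L * d)), rev(taps), type = "open")
  y[(d + 1L):(d + length(x))]
}

#' Cross-correlate a filtered channel with a period-3 impulse train
#'
#' The raw correlation sum at lag \code{j} between the signal and an
#' impulse train of period \code{period} with \code{trainLength / period}
#' impulses:
#' \deqn{c[j] = \sum_{k=0}^{N_\delta - 1} B[j + k N_p],}
#' with out-of-range samples contributing zero.  Sliding \code{j} across
#' the sequence averages the waveform at one period phase; for a periodic
#' signal plus zero-mean noise the noise term of \code{c[j] / N_delta} has
#' variance shrinking as \code{1 / N_delta}.
#'
#' @param B filtered channel (numeric vector).
#' @param j lag, 0-based (0 aligns the first impulse with \code{B[1]}).
#' @param period impulse-train period in samples; default 3.
#' @param trainLength impulse-train length in samples, a multiple of
#'   \code{period}; default 270 (90 impulses).
#' @return the raw correlation sum (not squared, not normalised).
#' @export
crossCorrelateChannel <- function(B, j, period = 3L, trainLength = 270L) {
  if (j < 0) stop("lag j must be non-negative")
  if (trainLength %% period != 0L)
    stop("trainLength must be a multiple of period")
  nImp <- trainLength %/% period
  idx <- j + 1L + period * (seq_len(nImp) - 1L)
  idx <- idx[idx <= length(B)]
  sum(B[idx])
}

# Vectorised c[j] for every lag j = 0..N-1 at once. Per residue class of j
# mod period, the sums are moving window sums over the stride-subsampled
# channel, done with cumulative sums.
xcorrAllLags <- function(B, period = 3L, trainLength = 270L) {
  nImp <- trainLength %/% period
  N <- length(B)
  out <- numeric(N)
  for (r in seq_len(period)) {
    sub <- B[seq(r, N, by = period)]
    m <- length(sub)
    cs <- cumsum(c(0, sub))
    ends <- pmin(seq_len(m) + nImp - 1L, m)
    out[seq(r, N, by = period)] <- cs[ends + 1L] - cs[seq_len(m)]
  }
  out
}

#' Combine per-channel correlations into the period-3 energy
#'
#' Each channel's correlation sum is squared and the four squares added:
#' \code{M = cA^2 + cT^2 + cC^2 + cG^2}.  Squaring per channel keeps each
#' contribution non-negative and mirrors the |X|^2 structure of the DFT
#' spectral-content measure.
#'
#' @param cA,cT,cC,cG per-channel correlation values at one lag (scalars or
#'   equal-length vectors).
#' @return the combined energy, always >= 0.
#' @export
combineEnergy <- function(cA, cT, cC, cG) {
  cA^2 + cT^2 + cC^2 + cG^2
}

#' Score a sequence for period-3 (coding) content
#'
#' The full detector chain for one sequence: Voss indicator encoding, FIR
#' bandpass emphasis of the 2*pi/3 component on each channel,
#' cross-correlation of each filtered channel with a period-3 impulse train
#' at every lag, per-channel squaring and summation into the energy track
#' M[j], an optional centred 3-lag moving average that removes the phase
#' ripple of the lagged correlation, and window-centre alignment (the score
#' of lag j is assigned to sequence position j + L/2, so peaks sit over
#' exons rather than at their left edges).  Margins where the impulse train
#' does not fit are zero.
#'
#' Pass the result to \code{\link{denoiseTrack}} for the wavelet-denoised
#' track used for calling.
#'
#' @param x sequence (character, \code{DNAString}, or single-element
#'   \code{DNAStringSet}).
#' @param trainLength impulse-train length L in bases (multiple of
#'   \code{period}); default 270.
#' @param period impulse-train period; default 3.
#' @param firOrder,centerFreq,halfBandwidth,window FIR design parameters,
#'   see \code{\link{designFir}}.
#' @param phaseSmooth apply the centred 3-lag moving average (default TRUE).
#' @param seqId identifier for the track; defaults to the sequence name.
#' @return a \code{\link{ScoreTrack}} with one value per base.
#' @export
scoreSequence <- function(x, trainLength = 270L, period = 3L,
                          firOrder = 8L, centerFreq = 2 * pi / 3,
                          halfBandwidth = 0.05, window = "hamming",
                          phaseSmooth = TRUE, seqId = NULL) {
  if (is(x, "DNAStringSet")) {
    if (is.null(seqId) && !is.null(names(x))) seqId <- names(x)[1L]
    x <- as.character(x[[1L]])
  } else if (is(x, "DNAString")) {
    x <- as.character(x)
  }
  if (is.null(seqId)) seqId <- "seq"
  N <- nchar(x)
  if (N < period) stop("sequence shorter than the impulse-train period")
  ind <- encodeIndicators(x, seqId = seqId)
  taps <- designFir(order = firOrder, centerFreq = centerFreq,
                    halfBandwidth = halfBandwidth, window = window)
  M <- numeric(N)
  for (b in c("A", "T", "C", "G")) {
    B <- applyFir(taps, as.numeric(indicatorChannel(ind, b)))
    M <- M + xcorrAllLags(B, period = period, trainLength = trainLength)^2
  }
  if (phaseSmooth && N >= 3L) {
    Ms <- as.numeric(stats::filter(M, rep(1 / 3, 3L), sides = 2L))
    Ms[is.na(Ms)] <- M[is.na(Ms)]
    M <- Ms
  }
  half <- trainLength %/% 2L
  if (half > 0L && half < N) {
    M <- c(numeric(half), M[seq_len(N - half)])
  } else if (half >= N) {
    M <- numeric(N)
  }
  new("ScoreTrack", seqId = seqId, values = pmax(M, 0),
      offset = 1L, windowLength = as.integer(trainLength),
      method = "xcorr")
}
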