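# Synthetic genomes with codon-biased exons and near-i.i.d. introns.
#
# The generator emulates the mechanism behind the period-3 property of
# coding DNA: non-uniform codon usage makes particular nucleotides recur
# at particular codon positions (e.g. abundant GCN codons place G and C at
# the first and second position of many codons), so exon indicator
# channels carry a 2*pi/3 spectral line that i.i.d. introns lack.

#' The 61 sense codons
#' @return character vector of the 61 codons that are not stop codons.
#' @export
senseCodons <- function() {
  b <- c("T", "C", "A", "G")
  all64 <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE),
                 1L, paste0, collapse = "")
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Default biased codon usage
#'
#' Weight 8 on the four alanine codons (GCA, GCC, GCG, GCT) and 1 on every
#' other sense codon, normalised to probabilities.  This concentrates G at
#' the first and C at the second codon position, a sharp period-3 signal
#' of the kind abundant GCN codons create in real coding regions.
#'
#' @param favoured codons receiving the high weight.
#' @param weight weight multiplier for the favoured codons.
#' @return named probability vector over \code{\link{senseCodons}()}.
#' @export
defaultCodonWeights <- function(favoured = c("GCA", "GCC", "GCG", "GCT"),
                                weight = 8) {
  cods <- senseCodons()
  w <- rep(1, length(cods))
  names(w) <- cods
  w[favoured] <- weight
  w / sum(w)
}

# Draw and restore: keeps generator calls from disturbing the caller's RNG
# stream while staying reproducible for a given seed.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic genome with known exon truth
#'
#' Each sequence is built as alternating intron and exon segments: exon
#' segments are concatenated codons drawn i.i.d. from \code{codonWeights}
#' (lengths forced to multiples of 3, each exon an independent reading
#' frame starting at its first base), intron segments are i.i.d. draws
#' from \code{intronBaseProbs} (optionally a first-order Markov chain for
#' harder negatives).  Exons are separated by at least one intron base.
#' Deterministic given \code{seed}.
#'
#' The defaults emulate a compact eukaryotic gene neighbourhood: 10 kb
#' sequences carrying 4-7 exons of 120-360 bp with sharply biased codon
#' usage and uniform introns.
#'
#' @param nSequences number of sequences.
#' @param sequenceLength length of each sequence in bases.
#' @param exonCountRange integer (min, max) exons per sequence.
#' @param exonLengthRange (min, max) exon length in bases; lengths are
#'   rounded down to multiples of 3.
#' @param codonWeights probability vector over the 61 sense codons.
#' @param intronBaseProbs probability 4-vector over A, C, G, T.
#' @param intronMarkov optional 4x4 row-stochastic matrix (rows/cols
#'   A, C, G, T); when given, introns follow this first-order chain.
#' @param exonLayout optional list of two-column matrices (start, end),
#'   one per sequence, fixing the exon intervals exactly (lengths need not
#'   be multiples of 3; the codon run is truncated to fit).  Overrides the
#'   random placement.
#' @param seed integer seed; the generator is deterministic given it.
#' @return list with \code{sequences} (named \code{DNAStringSet}) and
#'   \code{annotation} (\code{GRanges} of exon truth intervals).
#' @export
generateGenome <- function(nSequences = 10L, sequenceLength = 10000L,
                           exonCountRange = c(4L, 7L),
                           exonLengthRange = c(120L, 360L),
                           codonWeights = defaultCodonWeights(),
                           intronBaseProbs = rep(0.25, 4),
                           intronMarkov = NULL,
                           exonLayout = NULL,
                           seed = 1L) {
  stopifnot(abs(sum(codonWeights) - 1) < 1e-8,
            abs(sum(intronBaseProbs) - 1) < 1e-8)
  cods <- senseCodons()
  stopifnot(length(codonWeights) == length(cods))
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    seqs <- character(nSequences)
    annStart <- list(); annEnd <- list(); annSeq <- list()
    for (s in seq_len(nSequences)) {
      if (is.null(exonLayout)) {
        nex <- if (exonCountRange[1] == exonCountRange[2]) exonCountRange[1]
               else sample(exonCountRange[1]:exonCountRange[2], 1L)
        layout <- placeExons(sequenceLength, nex, exonLengthRange)
      } else {
        layout <- exonLayout[[s]]
      }
      ch <- drawIntron(sequenceLength, intronBaseProbs, intronMarkov, bases)
      if (!is.null(layout) && nrow(layout)) {
        for (i in seq_len(nrow(layout))) {
          st <- layout[i, 1L]; en <- layout[i, 2L]
          ncod <- ceiling((en - st + 1L) / 3)
          run <- strsplit(paste(sample(cods, ncod, replace = TRUE,
                                       prob = codonWeights),
                                collapse = ""), "", fixed = TRUE)[[1L]]
          ch[st:en] <- run[seq_len(en - st + 1L)]
        }
        annStart[[s]] <- layout[, 1L]; annEnd[[s]] <- layout[, 2L]
        annSeq[[s]] <- rep(sprintf("synth%02d", s), nrow(layout))
      }
      seqs[s] <- paste(ch, collapse = "")
    }
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- sprintf("synth%02d", seq_len(nSequences))
    annotation <- if (length(annSeq)) {
      GenomicRanges::GRanges(
        unlist(annSeq),
        IRanges::IRanges(unlist(annStart), unlist(annEnd)))
    } else {
      GenomicRanges::GRanges(seqnames = character(0),
                             ranges = IRanges::IRanges())
    }
    list(sequences = sequences, annotation = annotation)
  })
}

drawIntron <- function(n, probs, markov, bases) {
  if (is.null(markov))
    return(sample(bases, n, replace = TRUE, prob = probs))
  stopifnot(all(dim(markov) == c(4L, 4L)),
            max(abs(rowSums(markov) - 1)) < 1e-8)
  ch <- character(n)
  state <- sample.int(4L, 1L, prob = probs)
  ch[1L] <- bases[state]
  for (i in seq_len(n - 1L)) {
    state <- sample.int(4L, 1L, prob = markov[state, ])
    ch[i + 1L] <- bases[state]
  }
  ch
}

# random non-overlapping exon intervals with >= 1 intron base between and
# around them; lengths are multiples of 3
placeExons <- function(seqLen, nExons, lengthRange) {
  if (nExons == 0L) return(matrix(integer(0), 0L, 2L))
  lmin <- max(3L, 3L * (lengthRange[1L] %/% 3L))
  lmax <- 3L * (lengthRange[2L] %/% 3L)
  nCod <- seq.int(lmin %/% 3L, lmax %/% 3L)
  lens <- 3L * if (length(nCod) == 1L) rep(nCod, nExons) else
    sample(nCod, nExons, replace = TRUE)
  free <- seqLen - sum(lens) - (nExons + 1L)
  if (free < 0L)
    stop("exons of total length ", sum(lens), " cannot fit in ", seqLen,
         " bases with one-base separations")
  cuts <- sort(sample.int(free + 1L, nExons, replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts, free)) + 1L
  starts <- integer(nExons)
  pos <- 0L
  for (i in seq_len(nExons)) {
    starts[i] <- pos + gaps[i] + 1L
    pos <- starts[i] + lens[i] - 1L
  }
  cbind(starts, starts + lens - 1L)
}

#' Seeded periodic template plus Gaussian noise
#'
#' Produces \code{template + q} where the template repeats a fixed pattern
#' of the stated period and \code{q} is i.i.d. Gaussian noise.  Used to
#' study the noise-suppression property of impulse-train cross-correlation
#' (the noise term of the normalised correlation has variance
#' \code{noiseSd^2 / N_delta}).
#'
#' @param signalPeriod template period in samples.
#' @param n output length.
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param template optional numeric vector of length \code{signalPeriod};
#'   default is a fixed ramp pattern.
#' @return list with \code{signal} (noisy vector) and \code{template}
#'   (the noise-free periodic vector of length \code{n}).
#' @export
makeNoisyPeriodic <- function(signalPeriod, n, noiseSd, seed = 1L,
                              template = NULL) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (n < signalPeriod) stop("n must be at least one period")
  if (is.null(template))
    template <- seq_len(signalPeriod) - (signalPeriod + 1) / 2
  stopifnot(length(template) == signalPeriod)
  clean <- rep_len(template, n)
  noisy <- withSeed(seed, clean + stats::rnorm(n, sd = noiseSd))
  list(signal = noisy, template = clean)
}
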