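#' Read DNA sequences from a FASTA file
#'
#' Residues are uppercased and every character outside A/C/G/T is replaced
#' by \code{N}, so downstream indicator channels stay strictly binary.
#' Record ids are the first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return a named \code{\link[Biostrings]{DNAStringSet}} over the alphabet
#'   \{A, C, G, T, N\}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgu"), fa)
#' readFasta(fa)  # ACGN
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("FASTA file is empty: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">"))
    stop("malformed FASTA header at line 1 of ", path,
         ": expected '>' record start")
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  chars <- gsub("[^ACGT]", "N", toupper(as.character(raw)))
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- vapply(strsplit(names(raw), "[ \t]+"), `[`, "", 1L)
  out
}

#' Read exon annotations from BED or GFF3
#'
#' Both dialects are converted to the internal convention of 1-based
#' inclusive coordinates (BED input is 0-based half-open and is shifted at
#' the boundary; GFF3 is already 1-based inclusive).  Overlapping or
#' book-ended intervals on the same sequence are merged.  Strand is read
#' but ignored: the detector is computed on the given strand only.
#'
#' @param path path to a BED or GFF3 file.
#' @param dialect \code{"bed"} or \code{"gff3"}; default guesses from the
#'   file extension.
#' @return a \code{\link[GenomicRanges]{GRanges}} of merged exon intervals,
#'   sorted, strand \code{*}.
#' @export
readAnnotations <- function(path, dialect = c("auto", "bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- switch(dialect,
    bed  = rtracklayer::import(path, format = "BED"),
    gff3 = rtracklayer::import(path, format = "GFF3"))
  if (any(IRanges::width(gr) < 1L))
    stop("annotation interval with end < start in ", path)
  gr <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  GenomicRanges::strand(gr) <- "*"
  sort(gr, ignore.strand = TRUE)
}

#' Write exon annotations to BED
#'
#' The inverse boundary conversion of \code{\link{readAnnotations}}:
#' internal 1-based inclusive intervals become 0-based half-open BED rows.
#'
#' @param annot a \code{GRanges} of exon intervals.
#' @param path output file path.
#' @export
writeAnnotations <- function(annot, path) {
  rtracklayer::export(annot, path, format = "BED")
  invisible(path)
}

#' Serialize a ScoreTrack to bedGraph
#'
#' Consecutive equal values are collapsed into constant runs (bedGraph
#' 0-based half-open intervals).  Scores are written at full double
#' precision, so \code{\link{readScoreTrack}} round-trips exactly to text
#' float precision.
#'
#' @param track a \code{\link{ScoreTrack}}.
#' @param path output file path.
#' @export
writeScoreTrack <- function(track, path) {
  stopifnot(is(track, "ScoreTrack"))
  v <- track@values
  if (length(v) == 0L) {
    gr <- GenomicRanges::GRanges(score = numeric(0))
  } else {
    r <- S4Vectors::Rle(v)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    gr <- GenomicRanges::GRanges(
      track@seqId,
      IRanges::IRanges(starts + track@offset - 1L,
                       ends + track@offset - 1L),
      score = S4Vectors::runValue(r))
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph score track written by [writeScoreTrack()]
#'
#' @param path bedGraph file path.
#' @param method provenance label to attach to the returned track.
#' @return a \code{ScoreTrack}.  Positions inside the covered span that the
#'   file does not mention get score 0.
#' @export
readScoreTrack <- function(path, method = "file") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L)
    return(new("ScoreTrack", seqId = NA_character_, values = numeric(0),
               offset = 1L, windowLength = NA_integer_, method = method))
  sid <- as.character(GenomicRanges::seqnames(gr)[1L])
  if (length(unique(GenomicRanges::seqnames(gr))) > 1L)
    stop("readScoreTrack expects a single-sequence bedGraph")
  off <- min(GenomicRanges::start(gr))
  n <- max(GenomicRanges::end(gr)) - off + 1L
  v <- numeric(n)
  for (i in seq_along(gr)) {
    v[(GenomicRanges::start(gr)[i] - off + 1L):
        (GenomicRanges::end(gr)[i] - off + 1L)] <- gr$score[i]
  }
  new("ScoreTrack", seqId = sid, values = v, offset = as.integer(off),
      windowLength = NA_integer_, method = method)
}

#' Write sequences and matching exon truth as a FASTA/BED fixture pair
#'
#' @param sequences a named \code{DNAStringSet}.
#' @param annot a \code{GRanges} of exon intervals on those sequences.
#' @param fastaPath,bedPath output paths.
#' @export
writeGenome <- function(sequences, annot, fastaPath, bedPath) {
  Biostrings::writeXStringSet(sequences, fastaPath)
  writeAnnotations(annot, bedPath)
  invisible(c(fastaPath, bedPath))
}
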