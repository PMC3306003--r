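#' Per-base truth labels from exon annotations
#'
#' @param truth a \code{GRanges} of exon intervals.
#' @param seqId sequence identifier to extract labels for.
#' @param n sequence length in bases.
#' @return logical vector of length \code{n}: TRUE at exonic positions.
#' @export
truthLabels <- function(truth, seqId, n) {
  lab <- logical(n)
  sel <- truth[as.character(GenomicRanges::seqnames(truth)) == seqId]
  if (length(sel)) {
    if (max(GenomicRanges::end(sel)) > n)
      stop("annotation extends past the end of sequence ", seqId)
    for (i in seq_along(sel))
      lab[GenomicRanges::start(sel)[i]:GenomicRanges::end(sel)[i]] <- TRUE
  }
  lab
}

# Pool per-position scores and truth labels over one track or a list of
# tracks.  Dataset-level metrics concatenate nucleotides across sequences
# (single summary numbers per dataset), rather than averaging
# per-sequence metrics.
pooledScoresLabels <- function(tracks, truth, requireMatch = FALSE) {
  if (is(tracks, "ScoreTrack")) tracks <- list(tracks)
  scores <- vector("list", length(tracks))
  labels <- vector("list", length(tracks))
  truthIds <- unique(as.character(GenomicRanges::seqnames(truth)))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    stopifnot(is(tr, "ScoreTrack"))
    if (requireMatch && length(truth) && !(tr@seqId %in% truthIds))
      stop("sequence id ", tr@seqId, " not present in the annotation")
    scores[[i]] <- tr@values
    labels[[i]] <- truthLabels(truth, tr@seqId, length(tr@values))
  }
  list(scores = unlist(scores), labels = unlist(labels))
}

#' Nucleotide-level confusion counts at a threshold
#'
#' A position is predicted exonic iff its score is >= \code{t} (ties are
#' called exon, so ROC thresholds coincide exactly with observed score
#' values).
#'
#' @param track a \code{\link{ScoreTrack}} or list of tracks.
#' @param truth exon truth intervals (\code{GRanges}, 1-based inclusive).
#' @param t score threshold.
#' @return a \code{\link{ConfusionCounts}}.
#' @export
confusionAtThreshold <- function(track, truth, t) {
  requireMatch <- is(track, "ScoreTrack")  # pooled lists may hold
                                           # all-intron sequences
  p <- pooledScoresLabels(track, truth, requireMatch = requireMatch)
  countsFromScores(p$scores, p$labels, t)
}

countsFromScores <- function(scores, labels, t) {
  pred <- scores >= t
  new("ConfusionCounts",
      TP = as.numeric(sum(pred & labels)),
      TN = as.numeric(sum(!pred & !labels)),
      FP = as.numeric(sum(pred & !labels)),
      FN = as.numeric(sum(!pred & labels)))
}

#' Sensitivity: proportion of exon nucleotides recovered
#'
#' \code{Sn = TP / (TP + FN)}.  A zero denominator yields 0 with a warning.
#'
#' @param counts a \code{\link{ConfusionCounts}}.
#' @return proportion in [0, 1].
#' @export
sensitivity <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  den <- counts@TP + counts@FN
  if (den == 0) {
    warning("no exon nucleotides in truth; sensitivity defined as 0")
    return(0)
  }
  counts@TP / den
}

#' Specificity: proportion of predicted exon nucleotides that are exonic
#'
#' \code{Sp = TP / (TP + FP)} (the gene-prediction convention, a positive
#' predictive value).  A zero denominator yields 0 with a warning.
#'
#' @param counts a \code{\link{ConfusionCounts}}.
#' @return proportion in [0, 1].
#' @export
specificity <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  den <- counts@TP + counts@FP
  if (den == 0) {
    warning("no predicted exon nucleotides; specificity defined as 0")
    return(0)
  }
  counts@TP / den
}

#' Approximate correlation (Burset-Guigo summary measure)
#'
#' \code{ACP} averages the conditional probabilities
#' TP/(TP+FN), TP/(TP+FP), TN/(TN+FN), TN/(TN+FP); terms with a zero
#' denominator are undefined and are omitted from the average (the
#' convention of the measure's original definition).  Then
#' \code{AC = (ACP - 0.5) * 2}, ranging over [-1, 1].
#'
#' @param counts a \code{\link{ConfusionCounts}}.
#' @return list with elements \code{ACP} and \code{AC}.
#' @export
approximateCorrelation <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  TP <- counts@TP; TN <- counts@TN; FP <- counts@FP; FN <- counts@FN
  terms <- c(if (TP + FN > 0) TP / (TP + FN),
             if (TP + FP > 0) TP / (TP + FP),
             if (TN + FN > 0) TN / (TN + FN),
             if (TN + FP > 0) TN / (TN + FP))
  if (length(terms) == 0L)
    stop("all four ACP terms are undefined (empty evaluation)")
  acp <- mean(terms)
  list(ACP = acp, AC = (acp - 0.5) * 2)
}

rocFromScores <- function(scores, labels) {
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("degenerate truth: need both exon and intron positions")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  cumTP <- cumsum(l)
  cumFP <- cumsum(!l)
  # one operating point per unique score value (threshold = that value,
  # prediction rule score >= t), plus the (0, 0) sentinel at +Inf
  last <- which(diff(s) != 0)
  keep <- c(last, length(s))
  thr <- c(Inf, s[keep])
  tpr <- c(0, cumTP[keep] / nPos)
  fpr <- c(0, cumFP[keep] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("RocCurve", thresholds = thr, tpr = tpr, fpr = fpr,
      auc = min(max(auc, 0), 1))
}

#' Nucleotide-level ROC curve and AUC
#'
#' Sweeps the threshold over every observed score value (descending, with a
#' +Inf sentinel) and integrates the curve by the trapezoidal rule.  The
#' resulting AUC equals the rank statistic: the fraction of (exon, intron)
#' position pairs whose scores are correctly ordered, ties counting 1/2.
#'
#' @param track a \code{\link{ScoreTrack}} or list of tracks (pooled).
#' @param truth exon truth intervals (\code{GRanges}).
#' @return a \code{\link{RocCurve}}.
#' @export
rocCurve <- function(track, truth) {
  p <- pooledScoresLabels(track, truth)
  rocFromScores(p$scores, p$labels)
}

#' False positives at a target sensitivity
#'
#' Selects the largest threshold whose sensitivity reaches
#' \code{targetSn} and reports the false-positive count, specificity and
#' approximate correlation there.  Comparing methods at matched
#' sensitivity (e.g. 10\%...60\%) is the standard way to compare exon
#' detectors whose score scales differ.
#'
#' @param track a \code{\link{ScoreTrack}} or list of tracks.
#' @param truth exon truth intervals (\code{GRanges}).
#' @param targetSn target sensitivity in (0, 1].
#' @return list with \code{threshold}, \code{FP}, \code{Sn}, \code{Sp},
#'   \code{AC}.
#' @export
fpAtSensitivity <- function(track, truth, targetSn) {
  stopifnot(targetSn > 0, targetSn <= 1)
  p <- pooledScoresLabels(track, truth)
  roc <- rocFromScores(p$scores, p$labels)
  ok <- which(roc@tpr >= targetSn)
  if (length(ok) == 0L)
    stop("target sensitivity ", targetSn, " is unreachable")
  i <- ok[1L]  # largest threshold reaching the target
  t <- roc@thresholds[i]
  cc <- countsFromScores(p$scores, p$labels, t)
  list(threshold = t, FP = cc@FP, Sn = sensitivity(cc),
       Sp = specificity(cc), AC = approximateCorrelation(cc)$AC)
}

#' Train a score threshold from labelled score values
#'
#' The threshold is the standard-deviation-weighted compromise between the
#' exon and intron score means:
#' \deqn{T = (sd_e \cdot mean_i + sd_i \cdot mean_e) / (sd_e + sd_i).}
#' With equal spreads it reduces to the midpoint of the two means; the
#' class with the tighter distribution pulls the threshold away from
#' itself.
#'
#' @param exonScores,intronScores numeric vectors of period-3 score values
#'   collected at exon and intron training positions (>= 2 values each).
#' @return a \code{\link{ThresholdModel}}.
#' @examples
#' m <- trainThreshold(c(90, 100, 110), c(15, 20, 25))
#' modelThreshold(m)
#' @export
trainThreshold <- function(exonScores, intronScores) {
  if (length(exonScores) < 2L || length(intronScores) < 2L)
    stop("need at least 2 score values per class")
  me <- mean(exonScores); se <- stats::sd(exonScores)
  mi <- mean(intronScores); si <- stats::sd(intronScores)
  if (se + si == 0) stop("both classes have zero score variance")
  new("ThresholdModel", meanExon = me, sdExon = se,
      meanIntron = mi, sdIntron = si,
      threshold = (se * mi + si * me) / (se + si))
}

#' Extract exon/intron training scores from tracks
#'
#' @param tracks a \code{\link{ScoreTrack}} or list of tracks.
#' @param truth exon truth intervals (\code{GRanges}).
#' @return list with numeric vectors \code{exon} and \code{intron}.
#' @export
labeledScores <- function(tracks, truth) {
  p <- pooledScoresLabels(tracks, truth)
  list(exon = p$scores[p$labels], intron = p$scores[!p$labels])
}

#' Call exon intervals from a score track
#'
#' Maximal runs of positions scoring >= \code{t}; runs separated by fewer
#' than \code{mergeGap} intronic bases are merged, then runs shorter than
#' \code{minLength} are dropped.  The defaults (0, 0) apply no
#' post-processing.
#'
#' @param track a \code{\link{ScoreTrack}}.
#' @param t score threshold.
#' @param minLength minimum called-exon length in bases.
#' @param mergeGap maximal gap bridged between neighbouring calls.
#' @return a \code{GRanges} of called exon intervals (1-based inclusive).
#' @export
callExons <- function(track, t, minLength = 0L, mergeGap = 0L) {
  stopifnot(is(track, "ScoreTrack"), is.finite(t))
  pred <- track@values >= t
  r <- S4Vectors::Rle(pred)
  ends <- cumsum(S4Vectors::runLength(r))
  starts <- ends - S4Vectors::runLength(r) + 1L
  keep <- S4Vectors::runValue(r)
  starts <- starts[keep] + track@offset - 1L
  ends <- ends[keep] + track@offset - 1L
  if (length(starts) == 0L)
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges()))
  gr <- GenomicRanges::GRanges(track@seqId, IRanges::IRanges(starts, ends))
  if (mergeGap > 0L)
    gr <- GenomicRanges::reduce(gr, min.gapwidth = mergeGap + 1L)
  gr[IRanges::width(gr) >= max(minLength, 1L)]
}

#' Threshold-sweep evaluation report
#'
#' One row per swept threshold with the confusion counts and the derived
#' Sn/Sp/AC measures, ready for TSV export, plus the ROC summary.
#'
#' @param track a \code{\link{ScoreTrack}} or list of tracks.
#' @param truth exon truth intervals (\code{GRanges}).
#' @param sensitivities sensitivity grid for the FP-at-Sn summary
#'   (default 10\%..60\%).
#' @param maxRows cap on the number of swept thresholds in the table
#'   (evenly subsampled when the track has more unique values); the ROC and
#'   AUC always use the full sweep.
#' @return list with \code{table} (data.frame), \code{roc}
#'   (\code{\link{RocCurve}}), \code{auc}, and \code{fpAtSn} (data.frame).
#' @export
evaluateTrack <- function(track, truth,
                          sensitivities = seq(0.1, 0.6, by = 0.1),
                          maxRows = 512L) {
  p <- pooledScoresLabels(track, truth)
  roc <- rocFromScores(p$scores, p$labels)
  thr <- roc@thresholds[-1L]  # drop the Inf sentinel for the table
  if (length(thr) > maxRows)
    thr <- thr[unique(round(seq(1L, length(thr), length.out = maxRows)))]
  rows <- lapply(thr, function(t) {
    cc <- countsFromScores(p$scores, p$labels, t)
    ac <- approximateCorrelation(cc)
    data.frame(threshold = t, TP = cc@TP, TN = cc@TN, FP = cc@FP,
               FN = cc@FN, Sn = sensitivity(cc), Sp = specificity(cc),
               AC = ac$AC)
  })
  fp <- lapply(sensitivities, function(sn) {
    r <- fpAtSensitivity(track, truth, sn)
    data.frame(targetSn = sn, threshold = r$threshold, FP = r$FP,
               Sn = r$Sn, Sp = r$Sp, AC = r$AC)
  })
  list(table = do.call(rbind, rows), roc = roc, auc = roc@auc,
       fpAtSn = do.call(rbind, fp))
}
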