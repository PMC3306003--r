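# Brute-force oracles and small fixtures shared across tests.  Each oracle
# is written as the most literal possible evaluation of its definition and
# stays independent of the package code paths it checks.

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# literal impulse-train correlation: build the shifted train, dot product
bruteXcorr <- function(B, j, period = 3, trainLength = 270) {
  train <- numeric(trainLength)
  train[seq(1, trainLength, by = period)] <- 1
  shifted <- c(numeric(j), train)
  n <- max(length(B), length(shifted))
  sum(c(B, numeric(n - length(B))) * c(shifted, numeric(n - length(shifted))))
}

# position-by-position confusion tally
bruteConfusion <- function(scores, labels, t) {
  TP <- 0; TN <- 0; FP <- 0; FN <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= t
    if (pred && labels[i]) TP <- TP + 1
    else if (pred && !labels[i]) FP <- FP + 1
    else if (!pred && labels[i]) FN <- FN + 1
    else TN <- TN + 1
  }
  c(TP = TP, TN = TN, FP = FP, FN = FN)
}

# AUC as the fraction of correctly ordered (exon, intron) pairs, ties 1/2
bruteAucPairs <- function(scores, labels) {
  e <- scores[labels]
  i <- scores[!labels]
  cmp <- outer(e, i, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# single DFT coefficient at bin Nw/3 of one window, evaluated literally
bruteDftWindow <- function(chars, w, windowLength) {
  S <- 0
  for (b in c("A", "T", "C", "G")) {
    acc <- 0 + 0i
    for (n in 0:(windowLength - 1)) {
      acc <- acc + (chars[w + n] == b) * exp(-2i * pi * n / 3)
    }
    S <- S + Mod(acc)^2
  }
  S
}

# exhaustive threshold scan for FP at a target sensitivity
bruteFpAtSn <- function(scores, labels, targetSn) {
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels)
  for (t in thr) {
    pred <- scores >= t
    if (sum(pred & labels) / nPos >= targetSn)
      return(list(threshold = t, FP = sum(pred & !labels)))
  }
  NULL
}

labelsFromGr <- function(gr, seqId, n) {
  lab <- logical(n)
  sel <- gr[as.character(GenomicRanges::seqnames(gr)) == seqId]
  for (i in seq_along(sel))
    lab[GenomicRanges::start(sel)[i]:GenomicRanges::end(sel)[i]] <- TRUE
  lab
}

# small synthetic genome reused by several files (built once per test run)
sharedGenome <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateGenome(nSequences = 2L, sequenceLength = 6000L,
                               seed = 2024L)
    cache
  }
})

# synthetic 8 kb genome with the published five-exon layout of the
# C. elegans gene F56F11.4 (exon positions 928-1039, 2528-2857, 4114-4377,
# 5465-5644, 7255-7605), codon-biased exon content
f56LayoutGenome <- function(seed = 1L) {
  layout <- cbind(c(928L, 2528L, 4114L, 5465L, 7255L),
                  c(1039L, 2857L, 4377L, 5644L, 7605L))
  generateGenome(nSequences = 1L, sequenceLength = 8000L,
                 exonLayout = list(layout), seed = seed)
}

fixturePath <- function(file) {
  system.file("extdata", file, package = "ExonScan", mustWork = TRUE)
}
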