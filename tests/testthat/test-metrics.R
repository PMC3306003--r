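mkTrack <- function(values, seqId = "s") {
  new("ScoreTrack", seqId = seqId, values = values, offset = 1L,
      windowLength = NA_integer_, method = "test")
}
mkTruth <- function(starts, ends, seqId = "s") {
  GenomicRanges::GRanges(seqId, IRanges::IRanges(starts, ends))
}

test_that("confusion counts split positions by threshold and truth", {
  tr <- mkTrack(c(9, 9, 1, 1))
  truth <- mkTruth(1, 2)
  cc <- confusionAtThreshold(tr, truth, 5)
  expect_equal(confusionAsVector(cc), c(TP = 2, TN = 2, FP = 0, FN = 0))
  cc0 <- confusionAtThreshold(tr, truth, 0)
  expect_equal(confusionAsVector(cc0), c(TP = 2, TN = 0, FP = 2, FN = 0))
  expect_error(confusionAtThreshold(tr, mkTruth(1, 2, "other"), 5),
               "not present")
  set.seed(17)
  for (rep in 1:20) {
    v <- round(runif(200), 2)
    st <- sort(sample(1:190, 2))
    truth <- mkTruth(st[1], st[2])
    t <- runif(1)
    cc <- confusionAtThreshold(mkTrack(v), truth, t)
    lab <- labelsFromGr(truth, "s", 200)
    expect_equal(confusionAsVector(cc), bruteConfusion(v, lab, t))
  }
})

test_that("sensitivity and specificity follow their definitions", {
  cc <- new("ConfusionCounts", TP = 80, TN = 0, FP = 20, FN = 20)
  expect_equal(sensitivity(cc), 0.8)
  expect_equal(specificity(cc), 0.8)
  degenerate <- new("ConfusionCounts", TP = 0, TN = 5, FP = 0, FN = 0)
  expect_warning(sn <- sensitivity(degenerate), "defined as 0")
  expect_equal(sn, 0)
  expect_warning(sp <- specificity(degenerate), "defined as 0")
  expect_equal(sp, 0)
})

test_that("approximate correlation averages the defined terms", {
  perfect <- new("ConfusionCounts", TP = 10, TN = 10, FP = 0, FN = 0)
  expect_equal(approximateCorrelation(perfect),
               list(ACP = 1, AC = 1))
  chance <- new("ConfusionCounts", TP = 25, TN = 25, FP = 25, FN = 25)
  expect_equal(approximateCorrelation(chance)$AC, 0)
  # TN+FN = 0 is the only undefined term here; the three defined terms are
  # TP/(TP+FN) = 1, TP/(TP+FP) = 1/2, TN/(TN+FP) = 0
  mixed <- new("ConfusionCounts", TP = 50, TN = 0, FP = 50, FN = 0)
  expect_equal(approximateCorrelation(mixed)$ACP, 0.5)
  expect_equal(approximateCorrelation(mixed)$AC, 0)
})

test_that("ROC sweep matches the pairwise ordering oracle", {
  perfect <- rocCurve(mkTrack(c(1, 1, 0, 0)), mkTruth(1, 2))
  expect_equal(rocAuc(perfect), 1)
  flat <- rocCurve(mkTrack(rep(2, 10)), mkTruth(3, 7))
  expect_equal(rocAuc(flat), 0.5)
  expect_error(rocCurve(mkTrack(1:4), mkTruth(1, 4)), "degenerate")
  set.seed(23)
  for (rep in 1:20) {
    v <- sample(0:9, 60, replace = TRUE) / 3
    st <- sort(sample(1:55, 2))
    truth <- mkTruth(st[1], st[2])
    roc <- rocCurve(mkTrack(v), truth)
    lab <- labelsFromGr(truth, "s", 60)
    expect_equal(rocAuc(roc), bruteAucPairs(v, lab), tolerance = 1e-12)
    expect_equal(roc@thresholds[1], Inf)
    expect_equal(utils::tail(roc@tpr, 1), 1)
    expect_equal(utils::tail(roc@fpr, 1), 1)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(41)
  v <- runif(300)
  truth <- mkTruth(40, 140)
  a1 <- rocAuc(rocCurve(mkTrack(v), truth))
  a2 <- rocAuc(rocCurve(mkTrack(exp(3 * v)), truth))
  a3 <- rocAuc(rocCurve(mkTrack(rank(v)), truth))
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("raising the threshold never raises TP or FP", {
  set.seed(43)
  v <- runif(150)
  truth <- mkTruth(30, 80)
  ts <- sort(runif(12))
  counts <- lapply(ts, function(t)
    confusionAsVector(confusionAtThreshold(mkTrack(v), truth, t)))
  tp <- vapply(counts, `[[`, 0, "TP")
  fp <- vapply(counts, `[[`, 0, "FP")
  expect_true(all(diff(tp) <= 0))
  expect_true(all(diff(fp) <= 0))
})

test_that("FP at target sensitivity matches an exhaustive threshold scan", {
  r <- fpAtSensitivity(mkTrack(c(5, 5, 1, 1)), mkTruth(1, 2), 0.5)
  expect_equal(r$FP, 0)
  flat <- fpAtSensitivity(mkTrack(rep(2, 10)), mkTruth(3, 7), 0.2)
  expect_equal(flat$FP, 5)  # single threshold calls everything
  set.seed(29)
  for (rep in 1:20) {
    v <- sample(0:20, 100, replace = TRUE)
    truth <- mkTruth(10, 40)
    target <- runif(1, 0.05, 0.95)
    got <- fpAtSensitivity(mkTrack(v), truth, target)
    lab <- labelsFromGr(truth, "s", 100)
    want <- bruteFpAtSn(v, lab, target)
    expect_equal(got$FP, want$FP)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("threshold training reproduces the weighted-mean rule", {
  # collections with exact statistics: mean 100 sd 10 / mean 20 sd 5
  m <- trainThreshold(c(90, 100, 110), c(15, 20, 25))
  expect_equal(modelThreshold(m), (10 * 20 + 5 * 100) / 15)
  expect_equal(modelThreshold(m), 46 + 2 / 3)
  # symmetric spreads give the midpoint
  m2 <- trainThreshold(c(0, 10), c(100, 110))
  expect_equal(modelThreshold(m2), (5 + 105) / 2)
  # equal means collapse regardless of spreads
  m3 <- trainThreshold(c(40, 60), c(49, 51))
  expect_equal(modelThreshold(m3), 50)
  expect_error(trainThreshold(5, c(1, 2)), "at least 2")
  expect_error(trainThreshold(c(3, 3), c(4, 4)), "zero score variance")
  # betweenness when classes separate
  expect_gt(modelThreshold(m), m@meanIntron)
  expect_lt(modelThreshold(m), m@meanExon)
})

test_that("trained threshold separates classes above chance on synthetic scores", {
  g <- sharedGenome()
  tracks <- lapply(seq_along(g$sequences), function(i)
    denoiseTrack(scoreSequence(as.character(g$sequences[[i]]),
                               seqId = names(g$sequences)[i])))
  ls <- labeledScores(tracks, g$annotation)
  expect_gt(mean(ls$exon) - mean(ls$intron),
            sqrt((var(ls$exon) + var(ls$intron)) / 2))
  m <- trainThreshold(ls$exon, ls$intron)
  cc <- confusionAtThreshold(tracks, g$annotation, modelThreshold(m))
  sn <- sensitivity(cc)
  fpr <- cc@FP / (cc@FP + cc@TN)
  expect_gt(sn, fpr + 0.2)  # strictly above the chance diagonal
})

test_that("exon calling extracts, merges and filters runs", {
  gr <- callExons(mkTrack(c(0, 5, 5, 0)), 3)
  expect_equal(GenomicRanges::start(gr), 2)
  expect_equal(GenomicRanges::end(gr), 3)
  gr2 <- callExons(mkTrack(c(5, 0, 5)), 3, mergeGap = 1L)
  expect_length(gr2, 1L)
  expect_equal(GenomicRanges::start(gr2), 1)
  expect_equal(GenomicRanges::end(gr2), 3)
  gr3 <- callExons(mkTrack(c(0, 5, 5, 0)), 3, minLength = 3L)
  expect_length(gr3, 0L)
  expect_length(callExons(mkTrack(rep(0, 5)), 3), 0L)
})

test_that("evaluateTrack reports a coherent sweep table", {
  g <- sharedGenome()
  tr <- denoiseTrack(scoreSequence(as.character(g$sequences[[1]]),
                                   seqId = names(g$sequences)[1]))
  ev <- evaluateTrack(tr, g$annotation, maxRows = 64L)
  expect_lte(nrow(ev$table), 64L)
  expect_true(all(ev$table$TP + ev$table$TN + ev$table$FP + ev$table$FN ==
                    length(trackValues(tr))))
  expect_equal(ev$auc, rocAuc(ev$roc))
  expect_equal(nrow(ev$fpAtSn), 6L)
  expect_true(all(diff(ev$fpAtSn$FP) >= 0))  # more sensitivity, more FP
})
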