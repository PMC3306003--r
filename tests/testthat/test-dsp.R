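test_that("FIR design peaks at the period-3 frequency", {
  taps <- designFir()
  expect_length(taps, 9L)
  expect_equal(taps, rev(taps))  # linear phase
  grid <- seq(0, pi, length.out = 1024L)
  H <- firResponse(taps, grid)
  peak <- grid[which.max(H)]
  # an order-8 windowed design has a broad main lobe whose maximum sits a
  # few milliradians off centre; 0.01 rad is < 0.5% of the band centre
  expect_lt(abs(peak - 2 * pi / 3), 0.01)
  expect_gte(firResponse(taps, 2 * pi / 3), firResponse(taps, 0))
  expect_gte(firResponse(taps, 2 * pi / 3), firResponse(taps, pi))
  expect_error(designFir(halfBandwidth = 0.4), "band edges")
  expect_error(designFir(centerFreq = 3.5), "centerFreq")
})

test_that("applyFir compensates group delay and respects the band", {
  taps <- designFir()
  expect_equal(applyFir(taps, numeric(50)), numeric(50))
  # passband tone comes through at passband gain, aligned in time
  x <- cos(2 * pi * (0:299) / 3)
  y <- applyFir(taps, x)
  gain <- firResponse(taps, 2 * pi / 3)
  expect_lt(abs(max(abs(y[100:200])) - gain), 0.05 * gain)
  # DC lies in the stopband
  yc <- applyFir(taps, rep(1, 300))
  expect_lt(max(abs(yc[50:250])), 0.2)
  expect_error(applyFir(taps, numeric(0)), "empty")
})

test_that("cross-correlation matches the explicit impulse-train oracle", {
  expect_equal(crossCorrelateChannel(rep(c(1, 0, 0), 90), 0), 90)
  expect_equal(crossCorrelateChannel(numeric(300), 17), 0)
  expect_error(crossCorrelateChannel(1:10, -1), "non-negative")
  set.seed(101)
  for (rep in 1:30) {
    B <- rnorm(sample(200:500, 1))
    j <- sample(0:(length(B) - 1), 1)
    expect_equal(crossCorrelateChannel(B, j),
                 bruteXcorr(B, j), tolerance = 1e-12)
  }
})

test_that("combineEnergy squares per channel and is sign-invariant", {
  expect_equal(combineEnergy(1, 2, 3, 4), 30)
  expect_equal(combineEnergy(0, 0, 0, 0), 0)
  expect_equal(combineEnergy(-1, 2, -3, 4), combineEnergy(1, 2, 3, 4))
})

test_that("scoreSequence equals the composition of its stages", {
  set.seed(5)
  s <- randomDna(600)
  L <- 90L
  tr <- scoreSequence(s, trainLength = L)
  # independent composition: encode -> FIR -> per-lag correlation ->
  # square/sum -> 3-lag MA -> center alignment
  ind <- encodeIndicators(s)
  taps <- designFir()
  M <- numeric(600)
  for (b in c("A", "T", "C", "G")) {
    B <- applyFir(taps, as.numeric(indicatorChannel(ind, b)))
    cj <- vapply(0:599, function(j)
      crossCorrelateChannel(B, j, trainLength = L), 0)
    M <- M + cj^2
  }
  Ms <- as.numeric(stats::filter(M, rep(1/3, 3), sides = 2))
  Ms[is.na(Ms)] <- M[is.na(Ms)]
  expected <- pmax(c(numeric(L / 2), Ms[1:(600 - L / 2)]), 0)
  expect_equal(trackValues(tr), expected, tolerance = 1e-12)
  expect_length(trackValues(tr), nchar(s))
})

test_that("codon-biased exons score above introns; homopolymers score ~0", {
  g <- f56LayoutGenome(seed = 31L)
  tr <- scoreSequence(g$sequences[1])
  lab <- labelsFromGr(g$annotation, "synth01", 8000L)
  expect_gt(mean(trackValues(tr)[lab]), 2 * mean(trackValues(tr)[!lab]))
  trA <- scoreSequence(strrep("A", 3000))
  expect_lt(max(trackValues(trA)), 0.01 * max(trackValues(tr)))
  expect_error(scoreSequence("AC"), "shorter")
})

test_that("AUC is insensitive to impulse-train length on a fixed genome", {
  g <- f56LayoutGenome(seed = 1L)
  s <- as.character(g$sequences[[1]])
  aucs <- vapply(c(150L, 270L, 510L), function(L)
    rocAuc(rocCurve(denoiseTrack(scoreSequence(s, trainLength = L,
                                               seqId = "synth01")),
                    g$annotation)), 0)
  expect_lt(diff(range(aucs)), 0.05)
})

test_that("normalized correlation noise variance shrinks as 1/N_delta", {
  sdq <- 1
  vars <- vapply(c(30L, 90L, 270L), function(Nd) {
    L <- 3L * Nd
    noise <- vapply(1:200, function(trial) {
      mp <- makeNoisyPeriodic(3L, L + 3L, sdq, seed = 1000L * Nd + trial)
      crossCorrelateChannel(mp$signal, 0, trainLength = L) / Nd -
        mp$template[1]
    }, 0)
    var(noise)
  }, 0)
  predicted <- sdq^2 / c(30, 90, 270)
  expect_true(all(vars / predicted > 0.5 & vars / predicted < 2))
  # consecutive ratios follow the 1/N_delta line within a factor of 2
  expect_true(all(abs(log(vars[-3] / vars[-1]) - log(3)) < log(2)))
})
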