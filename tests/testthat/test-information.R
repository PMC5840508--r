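test_that("equal-width quantization follows the binning contract", {
  expect_equal(quantizeBins(c(0, 1, 2, 3), 2), c(1L, 2L, 3L, 4L))
  expect_equal(quantizeBins(rep(2.5, 10), 2), rep(1L, 10))
  expect_equal(quantizeBins(c(-1, 1), 1), c(1L, 2L))
  # the maximum always lands in the top bin
  expect_equal(quantizeBins(c(0, 10), 3)[2], 8L)
  # uniform draws occupy the bins about evenly
  set.seed(1)
  occ <- tabulate(quantizeBins(runif(10000), 2), 4) / 10000
  expect_lt(max(abs(occ - 0.25)), 0.02)
})

test_that("plug-in mutual information matches brute-force evaluation", {
  # independence: a constant response carries nothing
  expect_equal(mutualInformation(rep(1L, 40), rep(1:4, 10)), 0)
  # deterministic relation between 4 equiprobable classes and 4 bins: 2 bits
  expect_equal(mutualInformation(rep(1:4, each = 10), rep(1:4, each = 10)), 2)
  # hand case: joint counts [[3,1],[1,3]]
  bins <- c(1, 1, 1, 2, 1, 2, 2, 2)
  labels <- c(1, 1, 1, 1, 2, 2, 2, 2)
  expect_equal(mutualInformation(bins, labels),
               bruteForceMI(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)))
  # random joint tables
  set.seed(2)
  for (rep in 1:20) {
    nC <- sample(2:4, 1); nB <- sample(2:4, 1)
    labs <- sample(nC, 60, replace = TRUE)
    labs[1:nC] <- 1:nC  # ensure every class present
    bins <- sample(nB, 60, replace = TRUE)
    mi <- mutualInformation(bins, labs)
    expect_equal(mi, bruteForceMI(unclass(table(labs, bins))),
                 tolerance = 1e-12)
    # bounds: non-negative, below both log2(classes) and log2(bins)
    expect_gte(mi, 0)
    expect_lte(mi, min(log2(nC), log2(nB)) + 1e-12)
  }
  expect_error(mutualInformation(1:3, 1:4), "length")
})

test_that("sub-ensemble averages resample within classes only", {
  x <- rbind(matrix(1, 1, 4), matrix(0, 5, 4))
  set.seed(3)
  sub <- subensembleAverages(x, c(9, rep(2, 5)), nAverages = 8,
                             trialsPerAverage = 3)
  expect_equal(nrow(sub$averages), 16)
  expect_equal(sub$labels, rep(c(2, 9), each = 8))
  # class 9 has a single trial: every one of its sub-averages equals it
  expect_true(all(sub$averages[sub$labels == 9, ] == 1))
  expect_true(all(sub$averages[sub$labels == 2, ] == 0))
})

test_that("sub-average variance matches the bootstrap mean variance", {
  set.seed(4)
  x <- matrix(rnorm(60), 60, 1)
  sub <- subensembleAverages(x, rep(1:2, each = 30), nAverages = 4000,
                             trialsPerAverage = 30)
  v1 <- var(sub$averages[sub$labels == 1, 1])
  # bootstrap variance of a mean of 30 draws with replacement:
  # (1/30) * (population variance of the class trials, denominator n)
  pop <- mean((x[1:30, 1] - mean(x[1:30, 1]))^2)
  expect_equal(v1, pop / 30, tolerance = 0.1)
})

test_that("ranking selects the top k with the documented tie-break", {
  idx <- buildCoefficientIndex(32, 64, 5)
  idx$channelRank <- 1
  set.seed(5)
  idx$infoBits <- runif(32)
  sel <- rankAndSelect(idx, 10)
  expect_equal(sel$infoBits, sort(idx$infoBits, decreasing = TRUE)[1:10])
  # all-equal information: coarse levels and early supports win
  idx$infoBits <- 1
  sel <- rankAndSelect(idx, 4)
  expect_equal(sel$level, c("A5", "D5", "D4", "D4"))
  expect_equal(sel$coeffId, 1:4)
  expect_error(rankAndSelect(idx, 33), "exceeds")
})

test_that("channel pooling ranks globally and may take all from one channel", {
  i1 <- buildCoefficientIndex(32, 64, 5, channel = "good")
  i2 <- buildCoefficientIndex(32, 64, 5, channel = "bad")
  i1$infoBits <- seq(1, 2, length.out = 32)
  i2$infoBits <- seq(0, 0.5, length.out = 32)
  sel <- poolChannels(list(i1, i2), 10)
  expect_equal(unique(sel$channel), "good")
  expect_equal(nrow(sel), 10)
  expect_error(poolChannels(list(i1, i2), 65), "exceeds")
})

test_that("the C++ information kernel equals the R reference path", {
  ts <- smallTrialSet(seed = 6)
  info <- coefficientInformation(ts, nSubaverages = 25, trialsPerAverage = 10,
                                 seed = 99)
  # replay the same bootstrap draws through the exported R primitives
  W <- haarDecompose(trialData(ts, "ch1"), 5)
  set.seed(99)
  idxByClass <- WaveletInfo:::.drawClassIndices(
    trialLabels(ts), seq_len(nTrials(ts)), 25, 10)
  labs <- rep(sort(unique(trialLabels(ts))), each = 25)
  ref <- vapply(seq_len(ncol(W)), function(p) {
    vals <- unlist(lapply(idxByClass, function(idx) {
      colMeans(matrix(W[idx, p], nrow = 10))
    }))
    mutualInformation(quantizeBins(vals, 2), labs)
  }, numeric(1))
  expect_equal(info$infoBits, ref, tolerance = 1e-12)
})

test_that("information concentrates where the class waveforms live", {
  ts <- simulateTrialSet(simulationConfig(trialsPerClass = 30), seed = 8)
  info <- coefficientInformation(ts, seed = 8)
  overlaps <- info$supportStartMs < 300 & info$supportEndMs > 100
  expect_gt(mean(info$infoBits[overlaps]), mean(info$infoBits[!overlaps]))
})

test_that("pure-noise information is a small bias that shrinks with averaging", {
  ts <- noiseTrialSet(nPerClass = 20, seed = 10)
  coarse <- coefficientInformation(ts, nSubaverages = 50, seed = 11)
  fine <- coefficientInformation(ts, nSubaverages = 400, seed = 11)
  expect_gt(mean(coarse$infoBits), 0)
  expect_lt(mean(fine$infoBits), mean(coarse$infoBits))
})
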