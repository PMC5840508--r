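test_that("waveforms match the closed-form Gaussian sum", {
  fs <- 256
  w <- makeWaveform(waveformSpec(1, 150, 15), 0, fs, 500)
  expect_equal(length(w), 128)
  t <- (0:127) / fs * 1000
  expect_equal(which.max(w), which.min(abs(t - 150)))
  expect_gt(max(w), 0.99)

  # two components: pointwise closed-form oracle
  spec <- waveformSpec(c(0.8, 0.6), c(180, 260), c(12, 20))
  w2 <- makeWaveform(spec, 0, fs, 500)
  oracle <- 0.8 * exp(-(t - 180)^2 / (2 * 12^2)) +
    0.6 * exp(-(t - 260)^2 / (2 * 20^2))
  expect_equal(w2, oracle, tolerance = 1e-12)
  # two local maxima near the two latencies
  peaks <- which(diff(sign(diff(w2))) == -2) + 1
  expect_equal(length(peaks), 2)
  expect_lt(max(abs(t[peaks] - c(180, 260))), 1000 / fs)

  # jitter shifts every component by the same amount
  wj <- makeWaveform(spec, 5, fs, 500)
  oracleJ <- 0.8 * exp(-(t - 185)^2 / (2 * 12^2)) +
    0.6 * exp(-(t - 265)^2 / (2 * 20^2))
  expect_equal(wj, oracleJ, tolerance = 1e-12)
})

test_that("a latency pushed outside the epoch is rejected", {
  expect_error(makeWaveform(waveformSpec(1, 498, 10), 5, 256, 500), "epoch")
  expect_error(makeWaveform(waveformSpec(1, 2, 10), -5, 256, 500), "epoch")
})

test_that("background noise is reproducible, zero-mean and spectrally shaped", {
  set.seed(9); a <- makeBackgroundNoise(128, 256)
  set.seed(9); b <- makeBackgroundNoise(128, 256)
  expect_identical(a, b)
  set.seed(10); expect_false(identical(a, makeBackgroundNoise(128, 256)))
  expect_lt(abs(mean(a)), 1e-12)
  expect_equal(mean(a^2), 1, tolerance = 1e-12)

  # with a flat 1/f part and a strong alpha bump, the average periodogram
  # must peak at the alpha centre
  spec <- noiseSpec(spectralExponent = 0, alphaGain = 50)
  set.seed(11)
  n <- 256; fs <- 256
  psd <- rowMeans(vapply(1:200, function(i) {
    Mod(fft(makeBackgroundNoise(n, fs, spec)))[1:(n / 2)]^2
  }, numeric(n / 2)))
  freqs <- (0:(n / 2 - 1)) * fs / n
  expect_equal(freqs[which.max(psd)], 10, tolerance = 1.01)
})

test_that("the default simulation has the stated shape and exact per-trial SNR", {
  ts <- simulateTrialSet(seed = 3)
  expect_equal(nTrials(ts), 400)
  expect_equal(nSamples(ts), 128)
  expect_equal(as.integer(table(trialLabels(ts))), rep(100L, 4))
  expect_equal(sort(unique(trialLabels(ts))), 1:4)

  # with zero jitter the clean waveform is known exactly, so the realized
  # pattern-power / noise-power ratio can be checked trial by trial
  cfg <- simulationConfig(trialsPerClass = 3, jitterMs = 0)
  ts0 <- simulateTrialSet(cfg, seed = 5)
  specs <- defaultClassSpecs()
  for (i in seq_len(nTrials(ts0))) {
    clean <- makeWaveform(specs[[trialLabels(ts0)[i]]], 0, 256, 500)
    noise <- trialData(ts0, "ch1")[i, ] - clean
    expect_equal(mean(clean^2) / mean(noise^2), 0.33, tolerance = 1e-10)
  }
})

test_that("degenerate limits and reproducibility hold", {
  cfg <- simulationConfig(trialsPerClass = 4, jitterMs = 0, snr = Inf)
  ts <- simulateTrialSet(cfg, seed = 2)
  m <- trialData(ts, "ch1")
  for (cl in 1:4) {
    rows <- which(trialLabels(ts) == cl)
    expect_equal(m[rows[1], ], m[rows[2], ])
    expect_equal(m[rows[1], ], m[rows[4], ])
  }
  a <- simulateTrialSet(smallConfig(), seed = 7)
  b <- simulateTrialSet(smallConfig(), seed = 7)
  expect_identical(trialData(a, "ch1"), trialData(b, "ch1"))
})

test_that("the class-ensemble average converges to the jitter-smoothed waveform", {
  cfg <- simulationConfig(nClasses = 1, trialsPerClass = 2000)
  ts <- simulateTrialSet(cfg, classSpecs = defaultClassSpecs()[1], seed = 4)
  avg <- colMeans(trialData(ts, "ch1"))
  # jitter-smoothed expectation: average the clean waveform over a fine grid
  # of the uniform +/-5 ms jitter
  grid <- seq(-5, 5, length.out = 201)
  expected <- rowMeans(vapply(grid, function(j) {
    makeWaveform(defaultClassSpecs()[[1]], j, 256, 500)
  }, numeric(128)))
  # tolerance from the noise SEM: noise power = pattern power / snr
  sem <- sqrt(mean(expected^2) / 0.33 / 2000)
  expect_lt(max(abs(avg - expected)), 5 * sem)
})

test_that("noise channels are label-free and aligned with their template", {
  ts <- smallTrialSet(seed = 1)
  nc <- simulateNoiseChannels(ts, 3, seed = 2)
  expect_equal(channelNames(nc), c("noise1", "noise2", "noise3"))
  expect_identical(trialLabels(nc), trialLabels(ts))
  multi <- bindChannels(ts, nc)
  expect_equal(length(channelNames(multi)), 4)
  expect_equal(nSamples(multi), nSamples(ts))
})
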