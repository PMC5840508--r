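test_that("naive Bayes fitting honours symmetry, floors and errors", {
  x <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 1)
  m <- fitNaiveBayes(x, rep(1:2, each = 3))
  expect_equal(unname(m$means[1, ]), unname(m$means[2, ]))
  expect_equal(unname(m$vars[1, ]), unname(m$vars[2, ]))
  # any test point ties -> first class in model order
  expect_equal(predictNaiveBayes(m, 5)$class, 1)

  expect_error(fitNaiveBayes(matrix(rnorm(4), 4, 1), c(1, 1, 1, 2)),
               "class 2")
  # constant feature gets a harmless unit variance
  mc <- fitNaiveBayes(matrix(1, 6, 1), rep(1:2, each = 3))
  expect_equal(as.vector(mc$vars), c(1, 1))
})

test_that("predictions follow the Gaussian likelihoods", {
  eps <- 0.01
  m <- fitNaiveBayes(matrix(c(-1, -1, -1 + eps, 1, 1, 1 + eps), ncol = 1),
                     rep(c("A", "B"), each = 3))
  expect_equal(predictNaiveBayes(m, 0.9)$class, "B")

  # unequal variances: closed-form two-Gaussian posterior oracle
  xa <- c(-2, 0, 2); xb <- c(0.9, 1.0, 1.1)
  m2 <- fitNaiveBayes(matrix(c(xa, xb), ncol = 1), rep(1:2, each = 3))
  for (x0 in c(-1.5, 0, 0.5, 1, 1.4, 3)) {
    la <- dnorm(x0, mean(xa), sd(xa))
    lb <- dnorm(x0, mean(xb), sd(xb))
    p <- predictNaiveBayes(m2, x0)
    expect_equal(p$class, if (la >= lb) 1 else 2)
    expect_equal(as.vector(p$posterior), c(la, lb) / (la + lb),
                 tolerance = 1e-9)
  }

  # multi-feature, 3 classes: brute-force density-product oracle
  set.seed(1)
  feats <- matrix(rnorm(30), 15, 2)
  labs <- rep(1:3, each = 5)
  m3 <- fitNaiveBayes(feats, labs)
  test <- matrix(rnorm(10), 5, 2)
  p <- predictNaiveBayes(m3, test)
  for (i in 1:5) {
    dens <- vapply(1:3, function(cl) {
      prod(dnorm(test[i, ], m3$means[cl, ], sqrt(m3$vars[cl, ])))
    }, numeric(1))
    expect_equal(p$class[i], which.max(dens))
    expect_equal(p$posterior[i, ], setNames(dens / sum(dens), 1:3),
                 tolerance = 1e-9)
  }
  expect_equal(unname(rowSums(p$posterior)), rep(1, 5))
  expect_error(predictNaiveBayes(m3, matrix(0, 1, 3)), "dimension")
})

test_that("naive Bayes agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(2)
  feats <- matrix(rnorm(80), 40, 2)
  labs <- factor(rep(1:2, each = 20))  # balanced, so priors coincide
  ours <- fitNaiveBayes(feats, rep(1:2, each = 20))
  theirs <- e1071::naiveBayes(data.frame(a = feats[, 1], b = feats[, 2]),
                              labs)
  test <- data.frame(a = rnorm(10), b = rnorm(10))
  expect_equal(predictNaiveBayes(ours, as.matrix(test))$class,
               as.integer(as.character(predict(theirs, test))))
})

test_that("leave-one-out decoding is perfect in the separable limit", {
  cfg <- smallConfig(trialsPerClass = 5, snr = Inf, jitterMs = 1)
  ts <- simulateTrialSet(cfg, seed = 2)
  res <- looDecode(ts, nSelect = 10, nSubaverages = 30, seed = 1)
  expect_equal(performance(res), 1.0)
  expect_equal(diag(confusionMatrix(res)), setNames(rep(1, 4), 1:4))
})

test_that("decoding is deterministic given the seed", {
  ts <- smallTrialSet(seed = 3)
  r1 <- looDecode(ts, nSelect = 8, nSubaverages = 30, seed = 5)
  r2 <- looDecode(ts, nSelect = 8, nSubaverages = 30, seed = 5)
  expect_identical(r1@predictedLabels, r2@predictedLabels)
  expect_identical(foldSelections(r1), foldSelections(r2))
})

test_that("the held-out trial never influences its fold's selection", {
  ts <- smallTrialSet(trialsPerClass = 6, seed = 4)
  res <- looDecode(ts, nSelect = 6, nSubaverages = 25, seed = 9)
  for (i in c(1, 10, 24)) {
    corrupted <- ts
    corrupted@data[["ch1"]][i, ] <- 1e3 * seq_len(nSamples(ts))
    resC <- looDecode(corrupted, nSelect = 6, nSubaverages = 25, seed = 9)
    expect_identical(foldSelections(resC)[i, ], foldSelections(res)[i, ])
  }
})

test_that("multichannel decoding is invariant to channel order", {
  ch1 <- smallTrialSet(seed = 5)
  ch2 <- simulateTrialSet(
    smallConfig(),
    classSpecs = list(waveformSpec(0.9, 300, 15), waveformSpec(0.9, 350, 15),
                      waveformSpec(0.9, 300, 40),
                      waveformSpec(c(0.5, 0.5), c(120, 380), c(12, 18))),
    seed = 55, channel = "ch2")
  ab <- looDecode(bindChannels(ch1, ch2), nSelect = 8, nSubaverages = 30,
                  seed = 6)
  ba <- looDecode(bindChannels(ch1, ch2), channels = c("ch2", "ch1"),
                  nSelect = 8, nSubaverages = 30, seed = 6)
  expect_equal(performance(ab), performance(ba))
  expect_identical(ab@predictedLabels, ba@predictedLabels)
  # same coefficients selected, compared channel-qualified
  tag <- function(res) {
    idx <- coefficientIndex(res)
    apply(foldSelections(res), 1, function(s) {
      paste(sort(paste(idx$channel[s], idx$coeffId[s])), collapse = ";")
    })
  }
  expect_identical(tag(ab), tag(ba))
})

test_that("an uninformative channel contributes almost no selections", {
  # at the benchmark trial count the sub-ensemble MI estimates separate
  # signal from noise coefficients cleanly
  ts <- smallTrialSet(trialsPerClass = 100, seed = 7)
  multi <- bindChannels(ts, simulateNoiseChannels(ts, 1, seed = 8))
  res <- looDecode(multi, nSelect = 8, seed = 7)
  idx <- coefficientIndex(res)
  fromNoise <- mean(idx$channel[as.vector(foldSelections(res))] == "noise1")
  expect_lt(fromNoise, 0.1)
})

test_that("duplicating a channel leaves performance unchanged", {
  ts <- smallTrialSet(seed = 9)
  dup <- ts
  dup@data <- c(ts@data, list(copy = trialData(ts, "ch1")))
  single <- looDecode(ts, nSelect = 8, nSubaverages = 30, seed = 3)
  doubled <- looDecode(dup, nSelect = 8, nSubaverages = 30, seed = 3)
  expect_identical(single@predictedLabels, doubled@predictedLabels)
})
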