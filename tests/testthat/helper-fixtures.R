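# Small simulated datasets used across tests (32-sample epochs keep the
# 5-level decomposition valid while staying fast).

smallConfig <- function(trialsPerClass = 10, snr = 0.33, jitterMs = 5) {
  simulationConfig(trialsPerClass = trialsPerClass, fsHz = 64, epochMs = 500,
                   snr = snr, jitterMs = jitterMs)
}

smallTrialSet <- function(seed = 1, ...) {
  simulateTrialSet(smallConfig(...), seed = seed)
}

# pure-noise two-class set (no class information by construction)
noiseTrialSet <- function(nPerClass = 10, nSamplesPow = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * nPerClass
  TrialSet(matrix(rnorm(n * 2^nSamplesPow), n, 2^nSamplesPow),
           labels = rep(1:2, each = nPerClass), fsHz = 64)
}

# explicit orthonormal Haar basis matrix (independent of the package's
# transform): rows are basis vectors in the [A_L, D_L, ..., D_1] ordering,
# time-ascending within each block
haarBasisMatrix <- function(n, nLevels) {
  rows <- list()
  for (k in seq_len(n / 2^nLevels) - 1) {
    v <- numeric(n)
    v[(k * 2^nLevels + 1):((k + 1) * 2^nLevels)] <- 2^(-nLevels / 2)
    rows[[length(rows) + 1]] <- v
  }
  for (j in rev(seq_len(nLevels))) {
    half <- 2^(j - 1)
    for (k in seq_len(n / 2^j) - 1) {
      v <- numeric(n)
      v[(k * 2^j + 1):(k * 2^j + half)] <- 2^(-j / 2)
      v[(k * 2^j + half + 1):((k + 1) * 2^j)] <- -2^(-j / 2)
      rows[[length(rows) + 1]] <- v
    }
  }
  do.call(rbind, rows)
}

# brute-force plug-in mutual information (bits) from a joint count table
bruteForceMI <- function(joint) {
  N <- sum(joint)
  p <- joint / N
  ps <- rowSums(p)
  pb <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log2(p[i, j] / (ps[i] * pb[j]))
      }
    }
  }
  unname(total)
}
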