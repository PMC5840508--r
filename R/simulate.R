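## Synthetic evoked-potential benchmark: Gaussian-shaped class waveforms with
## uniform latency jitter, embedded in spectrally shaped (1/f + alpha)
## phase-randomised background noise at a fixed per-trial SNR.

#' Describe a class waveform as a sum of Gaussian components
#'
#' @param amplitude peak amplitude of each component (signal units).
#' @param latencyMs centre (latency) of each component, ms post-stimulus.
#' @param sigmaMs standard deviation (width) of each component, ms; must be
#'   positive. Width controls the frequency content of the component.
#' @return a \code{data.frame} with one row per Gaussian component.
#' @examples
#' waveformSpec(c(0.55, 0.55), c(190, 265), c(12, 18))  # biphasic class
#' @export
waveformSpec <- function(amplitude, latencyMs, sigmaMs) {
  stopifnot(length(amplitude) == length(latencyMs),
            length(latencyMs) == length(sigmaMs),
            all(is.finite(amplitude)), all(is.finite(latencyMs)),
            all(sigmaMs > 0))
  data.frame(amplitude = amplitude, latencyMs = latencyMs, sigmaMs = sigmaMs)
}

#' Default four-class waveform set
#'
#' Four classes designed so that peak amplitude and latency alone cannot
#' separate them all: classes 1 and 2 share peak amplitude and latency and
#' differ only in width (shape); class 3 has a slightly smaller, later peak;
#' class 4 is a combination of two Gaussians.
#'
#' @return list of four [waveformSpec()] data.frames.
#' @export
defaultClassSpecs <- function() {
  list(
    waveformSpec(1.0, 150, 12),
    waveformSpec(1.0, 150, 35),
    waveformSpec(0.8, 210, 12),
    waveformSpec(c(0.55, 0.55), c(190, 265), c(12, 18))
  )
}

#' Background-noise spectral shape
#'
#' Target power spectrum of the surrogate background activity:
#' \eqn{P(f) = f^{-\alpha} + g \cdot P_{1/f}(f_c) \exp(-(f-f_c)^2/(2\sigma^2))}
#' with \eqn{\sigma} = \code{alphaBandwidthHz / 2}. \code{alphaGain} is
#' expressed as a multiple of the 1/f power floor at the alpha centre, so the
#' default \code{alphaGain = 2} puts the total power at the alpha peak at 3x
#' the floor — an alpha rhythm of realistic prominence for resting EEG.
#'
#' @param spectralExponent \eqn{\alpha} of the 1/f^alpha power decay.
#' @param alphaCenterHz centre of the alpha bump (Hz).
#' @param alphaBandwidthHz bump width (Hz); the Gaussian sigma is half of it.
#' @param alphaGain bump height as a multiple of the 1/f floor at the centre.
#' @return a list of class \code{"noiseSpec"}.
#' @export
noiseSpec <- function(spectralExponent = 1, alphaCenterHz = 10,
                      alphaBandwidthHz = 2, alphaGain = 2) {
  stopifnot(alphaCenterHz > 0, alphaBandwidthHz > 0, alphaGain >= 0)
  structure(list(spectralExponent = spectralExponent,
                 alphaCenterHz = alphaCenterHz,
                 alphaBandwidthHz = alphaBandwidthHz,
                 alphaGain = alphaGain),
            class = "noiseSpec")
}

#' Simulation configuration
#'
#' Defaults encode the benchmark conditions: 4 classes x 100 trials, 500-ms
#' post-stimulus epochs at 256 Hz (128 samples), latency jitter uniform in
#' +/-5 ms, and per-trial SNR (clean-pattern power over noise power) of 0.33,
#' i.e. background noise three times stronger than the evoked pattern.
#'
#' @param nClasses number of stimulus classes.
#' @param trialsPerClass trials simulated per class.
#' @param fsHz sampling rate, Hz.
#' @param epochMs epoch length, ms (epoch starts at stimulus onset).
#' @param jitterMs half-range of the uniform latency jitter, ms.
#' @param snr per-trial signal-to-noise power ratio; \code{Inf} for noiseless.
#' @param noise a [noiseSpec()].
#' @return a list of class \code{"simulationConfig"}.
#' @export
simulationConfig <- function(nClasses = 4, trialsPerClass = 100, fsHz = 256,
                             epochMs = 500, jitterMs = 5, snr = 0.33,
                             noise = noiseSpec()) {
  stopifnot(nClasses >= 1, trialsPerClass >= 1, fsHz > 0, epochMs > 0,
            jitterMs >= 0, snr > 0)
  structure(list(nClasses = nClasses, trialsPerClass = trialsPerClass,
                 fsHz = fsHz, epochMs = epochMs, jitterMs = jitterMs,
                 snr = snr, noise = noise),
            class = "simulationConfig")
}

## deterministic substream seeds below 2^31
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1013904223 * k) %% 2147483647)
}

#' Sample one clean (noise-free) class waveform
#'
#' Evaluates the sum of the spec's Gaussian components on the epoch's sample
#' grid, with every component shifted by the same latency jitter.
#'
#' @param spec a [waveformSpec()].
#' @param jitterMs latency shift applied to all components, ms.
#' @param fsHz sampling rate, Hz.
#' @param epochMs epoch length, ms.
#' @param t0Ms time of the first sample, ms.
#' @return numeric vector of \code{fsHz * epochMs / 1000} samples.
#' @examples
#' w <- makeWaveform(waveformSpec(1, 150, 15), 0, 256, 500)
#' which.max(w)  # sample nearest 150 ms
#' @export
makeWaveform <- function(spec, jitterMs = 0, fsHz = 256, epochMs = 500,
                         t0Ms = 0) {
  n <- round(fsHz * epochMs / 1000)
  t <- t0Ms + (seq_len(n) - 1) / fsHz * 1000
  mu <- spec$latencyMs + jitterMs
  if (any(mu < t0Ms | mu >= t0Ms + epochMs)) {
    stop("component latency + jitter (", paste(round(mu, 2), collapse = ", "),
         " ms) falls outside the epoch [", t0Ms, ", ", t0Ms + epochMs, ") ms")
  }
  x <- numeric(n)
  for (i in seq_len(nrow(spec))) {
    x <- x + spec$amplitude[i] * exp(-(t - mu[i])^2 / (2 * spec$sigmaMs[i]^2))
  }
  x
}

#' Generate one realisation of spectrally shaped background noise
#'
#' Phase-randomised surrogate: the target amplitude spectrum (square root of
#' the [noiseSpec()] power shape) is combined with uniform random phases under
#' Hermitian symmetry and inverted to the time domain; the mean is removed.
#' Uses the current R RNG state, so wrap in \code{set.seed()} for
#' reproducibility. Repeated calls give independent realisations with the
#' same expected power spectrum.
#'
#' @param nSamples number of samples (>= 2).
#' @param fsHz sampling rate, Hz.
#' @param spec a [noiseSpec()].
#' @return numeric vector of length \code{nSamples}, zero mean, unit power
#'   (mean square) up to the spectral shape normalisation.
#' @export
makeBackgroundNoise <- function(nSamples, fsHz = 256, spec = noiseSpec()) {
  stopifnot(nSamples >= 2)
  n <- as.integer(nSamples)
  freqs <- (0:(n %/% 2)) * fsHz / n
  pow <- numeric(length(freqs))
  pos <- freqs > 0
  pow[pos] <- freqs[pos]^(-spec$spectralExponent)
  floorAtCenter <- spec$alphaCenterHz^(-spec$spectralExponent)
  sigma <- spec$alphaBandwidthHz / 2
  pow <- pow + spec$alphaGain * floorAtCenter *
    exp(-(freqs - spec$alphaCenterHz)^2 / (2 * sigma^2))
  pow[1] <- 0  # no DC
  amp <- sqrt(pow)

  ## Hermitian-symmetric spectrum with random phases
  half <- length(freqs)
  phases <- runif(half, 0, 2 * pi)
  spec_c <- complex(modulus = amp, argument = phases)
  spec_c[1] <- 0
  if (n %% 2 == 0) spec_c[half] <- complex(real = amp[half] *
                                             sign(cos(phases[half])), imaginary = 0)
  full <- c(spec_c, Conj(rev(spec_c[2:(half - (n %% 2 == 0))])))
  x <- Re(fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  ## normalise to unit mean-square power
  p <- mean(x^2)
  if (p > 0) x <- x / sqrt(p)
  x
}

#' Simulate a labeled evoked-potential dataset
#'
#' For each trial: a fresh jitter draw shifts the class waveform, and a fresh
#' background-noise realisation is rescaled so that the realized per-trial
#' ratio (mean clean-pattern power) / (noise power) equals \code{config$snr}
#' exactly. Jitter and noise use separate RNG substreams derived from
#' \code{seed}, so either component is reproducible in isolation.
#'
#' @param config a [simulationConfig()].
#' @param classSpecs list of [waveformSpec()], one per class
#'   (default [defaultClassSpecs()]).
#' @param seed integer master seed.
#' @param channel channel name for the generated single channel.
#' @return a single-channel [TrialSet-class] with
#'   \code{nClasses * trialsPerClass} trials, labels \code{1..nClasses} in
#'   class blocks.
#' @examples
#' ts <- simulateTrialSet(simulationConfig(trialsPerClass = 5), seed = 1)
#' ts
#' @export
simulateTrialSet <- function(config = simulationConfig(),
                             classSpecs = defaultClassSpecs(),
                             seed = 1, channel = "ch1") {
  stopifnot(length(classSpecs) == config$nClasses)
  n <- round(config$fsHz * config$epochMs / 1000)
  if (2^round(log2(n)) != n) {
    warning("epoch length (", n, " samples) is not a power of two; ",
            "the default 5-level wavelet decomposition will require padding")
  }
  nTrials <- config$nClasses * config$trialsPerClass
  labels <- rep(seq_len(config$nClasses), each = config$trialsPerClass)

  set.seed(.subSeed(seed, 1))
  jitters <- runif(nTrials, -config$jitterMs, config$jitterMs)

  X <- matrix(0, nTrials, n)
  cleanPower <- numeric(nTrials)
  for (i in seq_len(nTrials)) {
    w <- makeWaveform(classSpecs[[labels[i]]], jitters[i],
                      config$fsHz, config$epochMs)
    X[i, ] <- w
    cleanPower[i] <- mean(w^2)
  }

  if (is.finite(config$snr)) {
    set.seed(.subSeed(seed, 2))
    for (i in seq_len(nTrials)) {
      noise <- makeBackgroundNoise(n, config$fsHz, config$noise)
      targetPower <- if (cleanPower[i] > 0) cleanPower[i] / config$snr else 1
      X[i, ] <- X[i, ] + noise * sqrt(targetPower / mean(noise^2))
    }
  }

  cfgProv <- unclass(config)
  cfgProv$noise <- unclass(cfgProv$noise)
  TrialSet(X, labels, fsHz = config$fsHz, t0Ms = 0, channel = channel,
           provenance = list(generator = "simulateTrialSet", seed = seed,
                             config = cfgProv))
}

#' Pure background-noise channels matched to an existing TrialSet
#'
#' Generates channels that carry no class information: every trial is an
#' independent background-noise realisation of unit power, with the labels,
#' sampling rate and epoch of \code{like}. Used to probe robustness of
#' multichannel pooling against uninformative channels.
#'
#' @param like a [TrialSet-class] providing trial count, labels and timing.
#' @param nChannels number of noise channels to generate.
#' @param spec a [noiseSpec()].
#' @param seed integer seed.
#' @return a [TrialSet-class] of \code{nChannels} noise channels; combine
#'   with the original via [bindChannels()].
#' @export
simulateNoiseChannels <- function(like, nChannels = 8, spec = noiseSpec(),
                                  seed = 1) {
  n <- nSamples(like)
  data <- vector("list", nChannels)
  set.seed(.subSeed(seed, 3))
  for (ch in seq_len(nChannels)) {
    m <- matrix(0, nTrials(like), n)
    for (i in seq_len(nTrials(like))) {
      m[i, ] <- makeBackgroundNoise(n, samplingRate(like), spec)
    }
    data[[ch]] <- m
  }
  names(data) <- paste0("noise", seq_len(nChannels))
  new("TrialSet", data = data, labels = trialLabels(like),
      fsHz = samplingRate(like), t0Ms = epochStart(like),
      provenance = list(generator = "simulateNoiseChannels", seed = seed))
}
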