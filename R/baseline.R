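## Comparison baseline: single-trial peak amplitude / latency decoding.

#' Remove the least-squares linear trend from trials
#'
#' @param x numeric vector (one trace), a trials x samples matrix, or a
#'   [TrialSet-class] (all channels are detrended).
#' @return the detrended input, same shape/class.
#' @export
detrendTrials <- function(x) {
  if (is(x, "TrialSet")) {
    x@data <- lapply(x@data, .detrendMatrix)
    return(x)
  }
  if (is.null(dim(x))) .detrendMatrix(matrix(x, 1))[1, ] else .detrendMatrix(x)
}

.detrendMatrix <- function(m) {
  n <- ncol(m)
  stopifnot(n >= 2)
  D <- cbind(1, seq_len(n))
  ## residuals of the per-trial least-squares line, all trials at once
  coefs <- solve(crossprod(D), crossprod(D, t(m)))
  m - t(D %*% coefs)
}

#' Wavelet denoising against a pre-stimulus baseline
#'
#' A simplified single-trial denoiser: per decomposition level, the
#' distribution of baseline-period coefficients (supports entirely
#' pre-stimulus, pooled over trials) provides a mean and SD; post-stimulus
#' coefficients whose magnitude z-scored against that distribution stays
#' below \code{zThreshold} are zeroed, and the trials are reconstructed from
#' the surviving coefficients. With \code{zThreshold = 0} nothing is zeroed
#' and the reconstruction is the identity. Epochs without pre-stimulus
#' samples cannot provide a baseline: the operation then degrades to the
#' identity with a warning.
#'
#' @param trials a [TrialSet-class].
#' @param zThreshold z-score below which a post-stimulus coefficient is
#'   considered baseline-like and zeroed.
#' @param nLevels wavelet decomposition depth.
#' @return the denoised [TrialSet-class].
#' @export
denoiseTrials <- function(trials, zThreshold = 3, nLevels = 5) {
  if (epochStart(trials) >= 0) {
    warning("no pre-stimulus samples: denoising skipped (identity)")
    return(trials)
  }
  fs <- samplingRate(trials)
  n <- nSamples(trials)
  idx <- buildCoefficientIndex(n, fs, nLevels, t0Ms = epochStart(trials))
  baselineCoefs <- idx$supportEndMs <= 0
  if (!any(baselineCoefs)) {
    warning("pre-stimulus period shorter than the coarsest wavelet support: ",
            "denoising skipped (identity)")
    return(trials)
  }
  postCoefs <- which(!baselineCoefs)
  trials@data <- lapply(trials@data, function(m) {
    W <- haarDecompose(m, nLevels)
    for (lev in unique(idx$level)) {
      base <- which(baselineCoefs & idx$level == lev)
      if (!length(base)) next
      vals <- as.vector(W[, base])
      mu <- mean(vals); s <- sd(vals)
      if (!is.finite(s) || s == 0) next
      post <- postCoefs[idx$level[postCoefs] == lev]
      z <- abs(W[, post, drop = FALSE] - mu) / s
      W[, post][z < zThreshold] <- 0
    }
    haarReconstruct(W, nLevels)
  })
  trials
}

#' Extract a single-trial peak (amplitude and latency)
#'
#' Finds the extremum of the requested polarity inside a half-open time
#' window. An interior local extremum (a sample not smaller/larger than both
#' neighbours) is preferred; when the trace is monotone in the window, the
#' window-edge extremum is returned and flagged with \code{edge = TRUE}.
#'
#' @param x numeric trace (one trial).
#' @param fsHz sampling rate, Hz.
#' @param windowMs half-open search window \code{c(start, end)} in ms
#'   relative to stimulus onset; \code{NULL} means the whole epoch.
#' @param polarity \code{"positive"} (local maximum) or \code{"negative"}
#'   (local minimum).
#' @param t0Ms time of the first sample, ms.
#' @return list with \code{amplitude}, \code{latencyMs}, \code{edge}.
#' @examples
#' w <- makeWaveform(waveformSpec(1, 150, 15), 0, 256, 500)
#' extractPeak(w, 256, c(120, 200))
#' @export
extractPeak <- function(x, fsHz, windowMs = NULL, polarity = c("positive",
                        "negative"), t0Ms = 0) {
  polarity <- match.arg(polarity)
  n <- length(x)
  t <- t0Ms + (seq_len(n) - 1) / fsHz * 1000
  if (is.null(windowMs)) windowMs <- c(t0Ms, t0Ms + n / fsHz * 1000)
  inWin <- which(t >= windowMs[1] & t < windowMs[2])
  if (!length(inWin)) {
    stop("window [", windowMs[1], ", ", windowMs[2],
         ") ms contains no samples of the epoch")
  }
  s <- if (polarity == "negative") -x else x
  w <- s[inWin]
  len <- length(w)
  cand <- integer(0)
  if (len >= 3) {
    interior <- 2:(len - 1)
    isMax <- w[interior] >= w[interior - 1] & w[interior] >= w[interior + 1] &
      (w[interior] > w[interior - 1] | w[interior] > w[interior + 1])
    cand <- interior[isMax]
  }
  if (length(cand)) {
    best <- cand[which.max(w[cand])]
    edge <- FALSE
  } else {
    best <- which.max(w)
    edge <- TRUE
  }
  i <- inWin[best]
  list(amplitude = x[i], latencyMs = t[i], edge = edge)
}

#' Leave-one-out peak-feature decoding
#'
#' The baseline decoder: features are the single-trial peak amplitude (and
#' optionally latency) extracted from detrended (and optionally denoised)
#' trials of one channel, classified with the same uniform-prior Gaussian
#' naive Bayes and leave-one-out protocol as [looDecode()]. Feature
#' extraction is per-trial, so only model fitting is fold-dependent.
#'
#' @param trials a [TrialSet-class].
#' @param channel channel to use (default the first).
#' @param windowMs peak search window, as in [extractPeak()].
#' @param polarity peak polarity.
#' @param useLatency add peak latency as a second feature.
#' @param detrend remove the per-trial linear trend before peak extraction.
#' @param denoise apply [denoiseTrials()] first (requires pre-stimulus
#'   samples; silently skipped otherwise with a warning from the denoiser).
#' @param zThreshold denoising threshold, see [denoiseTrials()].
#' @return a [DecodingResult-class] with method \code{"peak"} or
#'   \code{"peak+latency"}.
#' @export
peakDecode <- function(trials, channel = channelNames(trials)[1],
                       windowMs = NULL, polarity = "positive",
                       useLatency = FALSE, detrend = TRUE, denoise = FALSE,
                       zThreshold = 3) {
  labels <- trialLabels(trials)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 3)) stop("every class needs at least 3 trials")

  if (denoise) trials <- denoiseTrials(trials, zThreshold = zThreshold)
  m <- trialData(trials, channel)
  if (detrend) m <- .detrendMatrix(m)

  n <- nrow(m)
  feats <- t(vapply(seq_len(n), function(i) {
    p <- extractPeak(m[i, ], samplingRate(trials), windowMs, polarity,
                     epochStart(trials))
    c(p$amplitude, p$latencyMs)
  }, numeric(2)))
  if (!useLatency) feats <- feats[, 1, drop = FALSE]

  pred <- integer(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    model <- .fitNB(feats[train, , drop = FALSE], labels[train], classes)
    ll <- .nbLogLik(model, feats[i, , drop = FALSE])
    pred[i] <- classes[max.col(ll, ties.method = "first")]
  }

  .decodingResult(labels, pred, classes,
                  selections = matrix(0L, 0, 0), index = data.frame(),
                  method = if (useLatency) "peak+latency" else "peak",
                  params = list(channel = channel, windowMs = windowMs,
                                polarity = polarity, useLatency = useLatency,
                                detrend = detrend, denoise = denoise))
}
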