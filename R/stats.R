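## Permutation significance and spatiotemporal selection-rate maps.

.shuffleSeed <- function(seed, shuffle) {
  as.integer((as.numeric(seed) + 15485863 * shuffle) %% 2147483647)
}

#' Permutation p-value from shuffle performances
#'
#' Default: the proportion of shuffle performances strictly above the
#' observed one. \code{"add-one"} computes \code{(r + 1) / (n + 1)}, which
#' can never be exactly zero (useful when a nonzero p is required downstream;
#' the default stays literal to the shuffle-count definition, with resolution
#' \code{1/n}).
#'
#' @param observed observed performance.
#' @param shuffled vector of shuffle performances.
#' @param correction \code{"none"} or \code{"add-one"}.
#' @return the p-value.
#' @export
permutationPValue <- function(observed, shuffled,
                              correction = c("none", "add-one")) {
  correction <- match.arg(correction)
  r <- sum(shuffled > observed)
  n <- length(shuffled)
  if (correction == "add-one") (r + 1) / (n + 1) else r / n
}

#' Label-permutation null distribution of decoding performance
#'
#' Reruns the entire wavelet-information pipeline — including the per-fold
#' coefficient selection — \code{nShuffles} times after randomly permuting
#' the trial labels (class counts are preserved by permutation). This is the
#' conservative construction: selection happens inside each fold on the
#' shuffled labels, so the null inherits any selection optimism of the
#' pipeline. Each shuffle uses an independent RNG substream derived from
#' \code{(seed, shuffle index)}.
#'
#' @param trials a [TrialSet-class].
#' @param nShuffles number of label permutations.
#' @param seed master seed (drives both the permutations and the decoding
#'   substreams).
#' @param correction p-value correction, see [permutationPValue()].
#' @param observed optionally, a precomputed observed [DecodingResult-class]
#'   (or performance value) to avoid rerunning the unshuffled decoding.
#' @param ... further arguments passed to [looDecode()] (channels, nSelect,
#'   nSubaverages, ...).
#' @return a [NullDistribution-class].
#' @export
permutationNull <- function(trials, nShuffles = 100, seed = 1,
                            correction = c("none", "add-one"),
                            observed = NULL, ...) {
  correction <- match.arg(correction)
  if (is.null(observed)) {
    observed <- looDecode(trials, seed = seed, ...)
  }
  obsPerf <- if (is(observed, "DecodingResult")) performance(observed)
             else as.numeric(observed)

  shuffled <- numeric(nShuffles)
  for (s in seq_len(nShuffles)) {
    ss <- .shuffleSeed(seed, s)
    set.seed(ss)
    permuted <- trials
    permuted@labels <- sample(trialLabels(trials))
    shuffled[s] <- performance(looDecode(permuted, seed = ss + 1L, ...))
  }
  new("NullDistribution", observed = obsPerf, shuffled = shuffled,
      pValue = permutationPValue(obsPerf, shuffled, correction),
      correction = correction)
}

#' NullDistribution accessors
#'
#' @param x a [NullDistribution-class].
#' @name NullDistribution-accessors
#' @aliases pValue nullPerformances
#' @return \code{pValue}: the permutation p-value; \code{nullPerformances}:
#'   the vector of shuffle performances.
NULL

#' @rdname NullDistribution-accessors
#' @export
setMethod("pValue", "NullDistribution", function(x) x@pValue)

#' @rdname NullDistribution-accessors
#' @export
setMethod("nullPerformances", "NullDistribution", function(x) x@shuffled)

setMethod("show", "NullDistribution", function(object) {
  n <- length(object@shuffled)
  cat("NullDistribution:", n, "label shuffles\n")
  cat(sprintf("  observed %.1f%%; null %.1f%% +/- %.1f%% (mean +/- sd)\n",
              100 * object@observed, 100 * mean(object@shuffled),
              100 * sd(object@shuffled)))
  cat(sprintf("  p = %.4g (%s; resolution 1/%d)\n", object@pValue,
              object@correction, n))
})

#' Selection-rate map: where and when information was used
#'
#' For every coefficient, the selection rate is the fraction of leave-one-out
#' folds in which it was among the selected set. These rates are aggregated
#' per (channel, post-stimulus sample) by averaging over the coefficients
#' whose time support includes that sample — one per decomposition level,
#' i.e. \code{nLevels + 1} coefficients per point.
#'
#' @param result a [DecodingResult-class] from [looDecode()] (must retain
#'   per-fold selections).
#' @return list of class \code{"selectionRateMap"} with
#'   \code{coefficients} (the coefficient index plus a \code{rate} column)
#'   and \code{byTime} (data.frame: \code{channel}, \code{timeMs},
#'   \code{rate}, one row per channel and sample).
#' @export
selectionRateMap <- function(result) {
  sel <- foldSelections(result)
  if (nrow(sel) == 0) {
    stop("the DecodingResult retains no per-fold selections ",
         "(feature-based decoders have none)")
  }
  index <- coefficientIndex(result)
  nFolds <- nrow(sel)
  rate <- tabulate(as.vector(sel), nbins = nrow(index)) / nFolds
  coefficients <- index
  coefficients$rate <- rate

  byTime <- do.call(rbind, lapply(split(coefficients, coefficients$channel),
                                  .channelTimeRates))
  rownames(byTime) <- NULL
  structure(list(coefficients = coefficients, byTime = byTime),
            class = "selectionRateMap")
}

.channelTimeRates <- function(coefs) {
  ## sample grid of this channel: the finest-level (D1) support spans 2
  ## samples, so the sample step is half of it
  fine <- coefs[coefs$levelRank == max(coefs$levelRank), ]
  dt <- (fine$supportEndMs[1] - fine$supportStartMs[1]) / 2
  times <- seq(min(coefs$supportStartMs), max(coefs$supportEndMs) - dt,
               by = dt)
  rate <- vapply(times, function(t) {
    mean(coefs$rate[coefs$supportStartMs <= t & coefs$supportEndMs > t])
  }, numeric(1))
  data.frame(channel = coefs$channel[1], timeMs = times, rate = rate,
             stringsAsFactors = FALSE)
}

#' @export
print.selectionRateMap <- function(x, ...) {
  cat("selectionRateMap:", nrow(x$coefficients), "coefficients over",
      length(unique(x$coefficients$channel)), "channel(s)\n")
  top <- x$coefficients[order(-x$coefficients$rate), ][1:5, ]
  cat("  top coefficients (channel level [start,end) ms -> rate):\n")
  for (i in 1:5) {
    cat(sprintf("   %s %s [%g, %g) -> %.2f\n", top$channel[i], top$level[i],
                top$supportStartMs[i], top$supportEndMs[i], top$rate[i]))
  }
  invisible(x)
}
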