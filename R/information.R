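## Information-driven coefficient selection.
##
## Single-trial coefficients are too noisy for direct information estimation,
## so each coefficient's mutual information with the class labels is computed
## on bootstrap sub-ensemble averages: many small with-replacement samples of
## trials from each class, averaged, then quantized into a few equal-width
## bins. The estimate is deliberately crude — it only has to RANK the
## coefficients, not measure information accurately.

#' Bootstrap sub-ensemble averages per class
#'
#' For each class, draws \code{nAverages} samples of \code{trialsPerAverage}
#' trials with replacement and averages them. Trials may recur within and
#' across sub-averages. Uses the current R RNG state; classes are processed
#' in ascending label order, each drawn with one \code{sample()} call of
#' \code{nAverages * trialsPerAverage} indices.
#'
#' @param x trials x variables numeric matrix (raw samples or wavelet
#'   coefficients — the transform is linear, so averaging commutes with it).
#' @param labels class label per row.
#' @param nAverages sub-ensemble averages per class.
#' @param trialsPerAverage trials drawn (with replacement) per average.
#' @return list with \code{averages} (a \code{nAverages * nClasses} x
#'   variables matrix, class blocks in ascending label order) and
#'   \code{labels}.
#' @export
subensembleAverages <- function(x, labels, nAverages = 200,
                                trialsPerAverage = 30) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (any(tabulate(match(labels, classes)) < 1)) stop("empty class")
  out <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    rows <- which(labels == classes[ci])
    idx <- rows[sample.int(length(rows), nAverages * trialsPerAverage,
                           replace = TRUE)]
    g <- rep(seq_len(nAverages), each = trialsPerAverage)
    out[[ci]] <- rowsum(x[idx, , drop = FALSE], g) / trialsPerAverage
  }
  list(averages = do.call(rbind, out),
       labels = rep(classes, each = nAverages))
}

#' Equal-width quantization
#'
#' Bins values into \code{2^nBits} equal-width bins spanning the min-max
#' range of the input; the maximum falls in the top bin and a constant input
#' falls entirely in the first bin.
#'
#' @param values finite numeric vector.
#' @param nBits number of quantization bits (bins = \code{2^nBits}).
#' @return integer bin indices in \code{1..2^nBits}.
#' @examples
#' quantizeBins(c(0, 1, 2, 3), 2)  # 1 2 3 4
#' @export
quantizeBins <- function(values, nBits = 2) {
  stopifnot(all(is.finite(values)), nBits >= 1)
  nBins <- 2L^nBits
  mn <- min(values); mx <- max(values)
  if (!(mx > mn)) return(rep(1L, length(values)))
  ## same expression order as the C++ kernel, for bit-identical binning
  b <- as.integer((values - mn) * (nBins / (mx - mn)))
  pmin(b, nBins - 1L) + 1L
}

#' Plug-in mutual information between bin indices and class labels
#'
#' \eqn{I = \sum_{s,b} P(s,b) \log_2 \frac{P(s,b)}{P(s) P(b)}} from the
#' empirical joint histogram, with \eqn{0 \log 0 = 0}. No bias correction is
#' applied: the value is used for ranking coefficients, not as an unbiased
#' information estimate.
#'
#' @param bins discrete response values (e.g. from [quantizeBins()]).
#' @param labels class label per observation.
#' @return mutual information in bits.
#' @export
mutualInformation <- function(bins, labels) {
  if (length(bins) != length(labels)) {
    stop("bins and labels must have the same length")
  }
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  joint <- table(labels, bins) / length(bins)
  ps <- rowSums(joint)
  pb <- colSums(joint)
  expected <- outer(ps, pb)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / expected[nz]))
}

## Draw per-class bootstrap indices (ascending class order) and compute the
## per-coefficient information for one channel's coefficient matrix via the
## C++ kernel. `trainRows` are the rows available (the fold's training set).
.drawClassIndices <- function(labels, trainRows, nAverages, trialsPerAverage) {
  classes <- sort(unique(labels[trainRows]))
  lapply(classes, function(cl) {
    rows <- trainRows[labels[trainRows] == cl]
    rows[sample.int(length(rows), nAverages * trialsPerAverage,
                    replace = TRUE)]
  })
}

.channelInfo <- function(coefMatrix, idxByClass, nAverages, trialsPerAverage,
                         quantBits) {
  fold_coef_info(coefMatrix, idxByClass, as.integer(nAverages),
                 as.integer(trialsPerAverage), as.integer(2^quantBits))
}

#' Estimate per-coefficient mutual information for a TrialSet
#'
#' Decomposes every trial of the requested channels with the orthonormal
#' Haar transform, forms bootstrap sub-ensemble averages in coefficient space
#' (averaging commutes with the linear transform), quantizes each
#' coefficient's sub-average values into \code{2^quantBits} equal-width bins
#' over their min-max range, and computes the plug-in mutual information with
#' the class labels.
#'
#' @param trials a [TrialSet-class].
#' @param channels channels to analyse (default all).
#' @param excludeTrials trial indices to leave out (e.g. a held-out trial).
#' @param nSubaverages sub-ensemble averages per class.
#' @param trialsPerAverage trials per sub-average (with replacement).
#' @param quantBits quantization bits.
#' @param nLevels wavelet decomposition depth.
#' @param seed optional seed for the bootstrap draws.
#' @param pad \code{"error"} (require dyadic epochs) or \code{"reflect"}
#'   (symmetric reflection padding; padded-region coefficients are flagged
#'   \code{inSupport = FALSE} and excluded from selection).
#' @return an information table: the coefficient index of all requested
#'   channels (see [buildCoefficientIndex()]) with columns \code{globalId},
#'   \code{channelRank} and \code{infoBits} appended.
#' @seealso [rankAndSelect()], [poolChannels()], [looDecode()]
#' @export
coefficientInformation <- function(trials, channels = channelNames(trials),
                                   excludeTrials = NULL,
                                   nSubaverages = 200, trialsPerAverage = 30,
                                   quantBits = 2, nLevels = 5, seed = NULL,
                                   pad = c("error", "reflect")) {
  pad <- match.arg(pad)
  dec <- .decomposeChannels(trials, channels, nLevels, pad)
  trainRows <- setdiff(seq_len(nTrials(trials)), excludeTrials)
  if (!is.null(seed)) set.seed(seed)
  idxByClass <- .drawClassIndices(trialLabels(trials), trainRows,
                                  nSubaverages, trialsPerAverage)
  info <- unlist(lapply(dec$coef, .channelInfo, idxByClass = idxByClass,
                        nAverages = nSubaverages,
                        trialsPerAverage = trialsPerAverage,
                        quantBits = quantBits))
  tab <- dec$index
  tab$infoBits <- info
  tab
}

#' Rank coefficients by information and select the top k
#'
#' Deterministic tie-break: larger information first, then coarser level
#' (A5 before D5 ... before D1), then earlier time support, then channel
#' order, then coefficient id. Coefficients flagged \code{inSupport = FALSE}
#' (padding artifacts) are never selected.
#'
#' @param info an information table from [coefficientInformation()] (or any
#'   data.frame with columns \code{infoBits}, \code{levelRank},
#'   \code{supportStartMs}, \code{channelRank}, \code{coeffId}).
#' @param k number of coefficients to select.
#' @return the selected rows of \code{info}, ordered by rank.
#' @export
rankAndSelect <- function(info, k = 25) {
  pool <- if (!is.null(info$inSupport)) info[info$inSupport, ] else info
  if (k > nrow(pool)) {
    stop("k = ", k, " exceeds the ", nrow(pool), " selectable coefficients")
  }
  cr <- if (is.null(pool$channelRank)) 0 else pool$channelRank
  ord <- order(-pool$infoBits, pool$levelRank, pool$supportStartMs, cr,
               pool$coeffId)
  pool[ord[seq_len(k)], ]
}

#' Pool per-channel information tables and select globally
#'
#' Concatenates the per-channel tables and applies [rankAndSelect()] to the
#' pool, so the k most informative coefficients are taken regardless of their
#' channel — a single channel may contribute all of them.
#'
#' @param infoTables list of per-channel information tables
#'   (from [coefficientInformation()] on single channels); channel rank is
#'   taken from list order when absent.
#' @param k number of coefficients to select from the pool.
#' @return the selected rows, ordered by rank.
#' @export
poolChannels <- function(infoTables, k = 25) {
  for (i in seq_along(infoTables)) {
    if (is.null(infoTables[[i]]$channelRank)) {
      infoTables[[i]]$channelRank <- i
    }
  }
  pool <- do.call(rbind, infoTables)
  rankAndSelect(pool, k)
}

## Decompose the requested channels once; returns list(coef = list of
## trials x P coefficient matrices, index = global index data.frame with
## globalId and channelRank).
.decomposeChannels <- function(trials, channels, nLevels, pad) {
  n <- nSamples(trials)
  padded <- n
  if (n %% 2^nLevels != 0) {
    if (pad == "error") {
      stop("epoch length ", n, " is not divisible by 2^", nLevels,
           "; use pad = \"reflect\" to enable symmetric reflection padding")
    }
    padded <- ceiling(n / 2^nLevels) * 2^nLevels
  }
  coef <- vector("list", length(channels))
  idx <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    m <- trialData(trials, channels[ci])
    if (padded != n) m <- .padReflect(m, nLevels)
    coef[[ci]] <- haarDecompose(m, nLevels)
    tab <- buildCoefficientIndex(padded, samplingRate(trials), nLevels,
                                 channel = channels[ci],
                                 t0Ms = epochStart(trials), nOriginal = n)
    ## rank by position in the TrialSet, not in the `channels` argument, so
    ## tie-breaks are invariant to the order channels are requested in
    tab$channelRank <- match(channels[ci], channelNames(trials))
    idx[[ci]] <- tab
  }
  index <- do.call(rbind, idx)
  index$globalId <- seq_len(nrow(index))
  rownames(index) <- NULL
  names(coef) <- channels
  list(coef = coef, index = index)
}
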