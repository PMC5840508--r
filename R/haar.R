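## Orthonormal Haar multiresolution decomposition.
##
## Coefficient ordering contract (part of the on-disk/selection contract):
## [A_L | D_L | D_{L-1} | ... | D_1], time-ascending within each block.
## Convention: detail at level j, translation k is
##   2^{-j/2} * (sum of the first 2^{j-1} samples - sum of the last 2^{j-1})
## over the half-open support [k*2^j, (k+1)*2^j) (0-based samples);
## approximation coefficients are 2^{-L/2} * block sums. This normalisation
## is orthonormal, so energy is conserved (Parseval) and the transform is
## its own inverse up to transposition.

#' Five-level Haar multiresolution decomposition
#'
#' Decomposes a sampled trace (or a matrix of traces) into detail scales
#' \code{D1..DL} plus the final approximation \code{AL}, using the orthonormal
#' Haar wavelet. The number of coefficients equals the number of samples, and
#' the transform conserves energy exactly.
#'
#' @param x numeric vector (one trial) or trials x samples matrix.
#' @param nLevels decomposition depth L (default 5, giving bands
#'   D1 = fs/4..fs/2 down to AL = 0..fs/2^(L+1)).
#' @return coefficients in the order \code{[AL, DL, ..., D1]}, each block
#'   time-ascending; a vector for vector input, a trials x coefficients
#'   matrix for matrix input.
#' @seealso [haarReconstruct()], [buildCoefficientIndex()]
#' @examples
#' x <- rnorm(32)
#' w <- haarDecompose(x, 3)
#' sum(w^2) - sum(x^2)  # ~ 0 (Parseval)
#' @export
haarDecompose <- function(x, nLevels = 5) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, 1) else as.matrix(x)
  n <- ncol(m)
  if (n %% 2^nLevels != 0) {
    stop("signal length ", n, " is not divisible by 2^", nLevels,
         "; use a dyadic epoch length or the reflection padding option ",
         "(pad = \"reflect\") of the decoding functions")
  }
  details <- vector("list", nLevels)
  a <- m
  for (j in seq_len(nLevels)) {
    odd <- a[, seq(1, ncol(a), 2), drop = FALSE]
    even <- a[, seq(2, ncol(a), 2), drop = FALSE]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  out <- do.call(cbind, c(list(a), details[rev(seq_len(nLevels))]))
  if (vec) out[1, ] else out
}

#' Inverse Haar transform, optionally masking coefficients
#'
#' Reconstructs the time-domain trace(s) from coefficients in the
#' [haarDecompose()] ordering. With a \code{keep} mask, masked-out
#' coefficients are zeroed before inversion, reconstructing only the retained
#' part of the signal.
#'
#' @param w numeric vector or trials x coefficients matrix of coefficients.
#' @param nLevels decomposition depth used to produce \code{w}.
#' @param keep optional logical vector (length = number of coefficients);
#'   \code{FALSE} entries are zeroed before inversion.
#' @return reconstructed trace(s), same shape as the input to
#'   [haarDecompose()].
#' @export
haarReconstruct <- function(w, nLevels = 5, keep = NULL) {
  vec <- is.null(dim(w))
  m <- if (vec) matrix(w, 1) else as.matrix(w)
  n <- ncol(m)
  if (!is.null(keep)) {
    stopifnot(length(keep) == n)
    m[, !keep] <- 0
  }
  nA <- n / 2^nLevels
  a <- m[, seq_len(nA), drop = FALSE]
  offset <- nA
  for (j in rev(seq_len(nLevels))) {
    nD <- n / 2^j
    d <- m[, offset + seq_len(nD), drop = FALSE]
    offset <- offset + nD
    up <- matrix(0, nrow(m), 2 * ncol(a))
    up[, seq(1, ncol(up), 2)] <- (a + d) / sqrt(2)
    up[, seq(2, ncol(up), 2)] <- (a - d) / sqrt(2)
    a <- up
  }
  if (vec) a[1, ] else a
}

#' Coefficient index: scale band and time support of every coefficient
#'
#' Maps each position of a [haarDecompose()] coefficient vector to its
#' decomposition level, translation, frequency band and half-open time
#' support. For the default \code{fs = 256} Hz, 5 levels, the detail bands
#' are D1 = 64-128, D2 = 32-64, D3 = 16-32, D4 = 8-16, D5 = 4-8 and
#' A5 = 0-4 Hz. Supports are \code{[k*2^j, (k+1)*2^j)} samples converted to
#' ms relative to stimulus onset.
#'
#' @param nSamples samples per trial (divisible by \code{2^nLevels}).
#' @param fsHz sampling rate, Hz.
#' @param nLevels decomposition depth.
#' @param channel channel name attached to every entry.
#' @param t0Ms time of the first sample, ms.
#' @param nOriginal for padded signals, the original (pre-padding) sample
#'   count; coefficients whose support starts at or beyond it are flagged
#'   \code{inSupport = FALSE} and excluded from selection.
#' @return data.frame with columns \code{coeffId}, \code{channel},
#'   \code{level} ("A5","D5",...,"D1"), \code{levelRank} (0 = coarsest),
#'   \code{k}, \code{bandLowHz}, \code{bandHighHz}, \code{supportStartMs},
#'   \code{supportEndMs}, \code{inSupport}; one row per coefficient.
#' @export
buildCoefficientIndex <- function(nSamples, fsHz = 256, nLevels = 5,
                                  channel = "ch1", t0Ms = 0,
                                  nOriginal = nSamples) {
  stopifnot(nSamples %% 2^nLevels == 0)
  blocks <- list()
  ## approximation block
  jA <- nLevels
  kA <- seq_len(nSamples / 2^jA) - 1
  blocks[[1]] <- data.frame(
    level = paste0("A", nLevels), levelRank = 0, k = kA,
    bandLowHz = 0, bandHighHz = fsHz / 2^(nLevels + 1),
    supportStart = kA * 2^jA, supportLen = 2^jA)
  ## detail blocks, coarse (DL) to fine (D1)
  for (j in rev(seq_len(nLevels))) {
    k <- seq_len(nSamples / 2^j) - 1
    blocks[[length(blocks) + 1]] <- data.frame(
      level = paste0("D", j), levelRank = nLevels - j + 1, k = k,
      bandLowHz = fsHz / 2^(j + 1), bandHighHz = fsHz / 2^j,
      supportStart = k * 2^j, supportLen = 2^j)
  }
  idx <- do.call(rbind, blocks)
  data.frame(
    coeffId = seq_len(nrow(idx)),
    channel = channel,
    level = idx$level,
    levelRank = idx$levelRank,
    k = idx$k,
    bandLowHz = idx$bandLowHz,
    bandHighHz = idx$bandHighHz,
    supportStartMs = t0Ms + idx$supportStart / fsHz * 1000,
    supportEndMs = t0Ms + (idx$supportStart + idx$supportLen) / fsHz * 1000,
    inSupport = idx$supportStart < nOriginal,
    stringsAsFactors = FALSE
  )
}

## reflection-pad a trials x samples matrix up to a multiple of 2^nLevels
.padReflect <- function(m, nLevels) {
  n <- ncol(m)
  target <- ceiling(n / 2^nLevels) * 2^nLevels
  if (target == n) return(m)
  extra <- target - n
  if (extra > n) stop("cannot reflect-pad: epoch shorter than the padding")
  cbind(m, m[, n:(n - extra + 1), drop = FALSE])
}
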