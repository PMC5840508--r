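#' TrialSet: labeled, epoched multichannel trials
#'
#' The universal input container: a set of trials, each a fixed-length sampled
#' voltage trace per channel, with one class label per trial. All channels
#' share the trial alignment and epoch length. Time is measured in ms relative
#' to stimulus onset; \code{t0Ms} is the time of the first sample (0 for
#' purely post-stimulus epochs, negative when a pre-stimulus baseline is
#' included).
#'
#' @slot data named list of numeric matrices, one per channel, each
#'   trials x samples.
#' @slot labels integer vector of class ids, one per trial.
#' @slot fsHz sampling rate in Hz.
#' @slot t0Ms time of the first sample relative to stimulus onset, ms.
#' @slot provenance free-form list recording how the object was made
#'   (seed, generator configuration, source files).
#'
#' @seealso [TrialSet()] for construction, [simulateTrialSet()],
#'   [readTrialSet()].
#' @export
setClass("TrialSet",
  representation(
    data = "list",
    labels = "integer",
    fsHz = "numeric",
    t0Ms = "numeric",
    provenance = "list"
  ),
  prototype(
    data = list(), labels = integer(), fsHz = 256, t0Ms = 0,
    provenance = list()
  )
)

setValidity("TrialSet", function(object) {
  msgs <- character()
  if (length(object@data) == 0L) {
    msgs <- c(msgs, "TrialSet must contain at least one channel")
  }
  if (is.null(names(object@data)) || anyNA(names(object@data)) ||
      any(names(object@data) == "")) {
    msgs <- c(msgs, "channels must be named")
  }
  if (anyDuplicated(names(object@data))) {
    msgs <- c(msgs, "channel names must be unique")
  }
  dims <- lapply(object@data, dim)
  if (any(vapply(object@data, function(m) !is.matrix(m) || !is.numeric(m),
                 logical(1)))) {
    msgs <- c(msgs, "each channel must be a numeric trials x samples matrix")
  } else {
    d0 <- dims[[1]]
    if (!all(vapply(dims, function(d) identical(d, d0), logical(1)))) {
      msgs <- c(msgs, "all channels must share (n_trials, n_samples)")
    }
    if (length(object@labels) != d0[1]) {
      msgs <- c(msgs, sprintf("labels length (%d) != number of trials (%d)",
                              length(object@labels), d0[1]))
    }
    if (any(vapply(object@data, function(m) any(!is.finite(m)), logical(1)))) {
      msgs <- c(msgs, "trial data must be finite")
    }
  }
  if (length(object@fsHz) != 1L || !is.finite(object@fsHz) || object@fsHz <= 0) {
    msgs <- c(msgs, "fsHz must be a single positive number")
  }
  if (length(object@t0Ms) != 1L || !is.finite(object@t0Ms)) {
    msgs <- c(msgs, "t0Ms must be a single finite number")
  }
  if (anyNA(object@labels)) msgs <- c(msgs, "labels must not contain NA")
  if (length(msgs)) msgs else TRUE
})

#' DecodingResult: predictions and performance of a cross-validated decoder
#'
#' Returned by [looDecode()] and [peakDecode()]. Holds per-trial true and
#' predicted labels, the per-fold selected coefficient ids (wavelet path
#' only), the coefficient index the selections refer to, the row-normalised
#' confusion matrix, and the aggregate performance (proportion of trials
#' correctly classified).
#'
#' @slot trueLabels integer, one per trial.
#' @slot predictedLabels integer, one per trial.
#' @slot performance proportion of trials correctly classified, in [0,1].
#' @slot confusion numeric matrix, rows = true class, columns = predicted
#'   class, each row summing to 1.
#' @slot foldSelections integer matrix, folds x K, global coefficient ids
#'   selected in each leave-one-out fold (0 x 0 for feature-based decoders).
#' @slot index data.frame coefficient index (see [buildCoefficientIndex()]),
#'   empty for feature-based decoders.
#' @slot method character, e.g. "wavelet-information" or "peak".
#' @slot params list of the decoding parameters used.
#' @export
setClass("DecodingResult",
  representation(
    trueLabels = "integer",
    predictedLabels = "integer",
    performance = "numeric",
    confusion = "matrix",
    foldSelections = "matrix",
    index = "data.frame",
    method = "character",
    params = "list"
  )
)

setValidity("DecodingResult", function(object) {
  msgs <- character()
  n <- length(object@trueLabels)
  if (length(object@predictedLabels) != n) {
    msgs <- c(msgs, "true and predicted label vectors differ in length")
  }
  if (length(object@performance) != 1L || object@performance < 0 ||
      object@performance > 1) {
    msgs <- c(msgs, "performance must be a single value in [0,1]")
  }
  if (n > 0) {
    rs <- rowSums(object@confusion)
    if (any(abs(rs - 1) > 1e-8)) {
      msgs <- c(msgs, "confusion matrix rows must sum to 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' NullDistribution: label-permutation null of decoding performance
#'
#' Returned by [permutationNull()]. The p-value is the proportion of shuffle
#' performances strictly above the observed performance; with
#' \code{correction = "add-one"} it is (r+1)/(n+1) so it can never be exactly
#' zero.
#'
#' @slot observed observed decoding performance.
#' @slot shuffled numeric vector of shuffle performances.
#' @slot pValue the permutation p-value.
#' @slot correction "none" or "add-one".
#' @export
setClass("NullDistribution",
  representation(
    observed = "numeric",
    shuffled = "numeric",
    pValue = "numeric",
    correction = "character"
  )
)

setValidity("NullDistribution", function(object) {
  msgs <- character()
  if (object@pValue < 0 || object@pValue > 1) {
    msgs <- c(msgs, "pValue must lie in [0,1]")
  }
  if (length(object@observed) != 1L) {
    msgs <- c(msgs, "observed must be a single performance value")
  }
  if (length(msgs)) msgs else TRUE
})
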