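#' Construct a TrialSet
#'
#' @param data a named list of numeric matrices (one per channel, each
#'   trials x samples), or a single matrix (treated as one channel).
#' @param labels vector of class labels, one per trial; coerced to integer.
#' @param fsHz sampling rate in Hz.
#' @param t0Ms time of the first sample relative to stimulus onset (ms).
#' @param channel channel name used when \code{data} is a single matrix.
#' @param provenance optional list describing the origin of the data.
#'
#' @return a validated [TrialSet-class] object.
#' @examples
#' ts <- TrialSet(matrix(rnorm(20 * 32), 20, 32),
#'                labels = rep(1:2, each = 10), fsHz = 64)
#' nTrials(ts)
#' @export
TrialSet <- function(data, labels, fsHz, t0Ms = 0, channel = "ch1",
                     provenance = list()) {
  if (is.matrix(data)) {
    data <- stats::setNames(list(data), channel)
  }
  data <- lapply(data, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  new("TrialSet", data = data, labels = as.integer(labels),
      fsHz = as.numeric(fsHz), t0Ms = as.numeric(t0Ms),
      provenance = provenance)
}

#' TrialSet accessors
#'
#' @param x a [TrialSet-class].
#' @param channel channel name or index.
#' @name TrialSet-accessors
#' @aliases nTrials nSamples channelNames trialLabels samplingRate epochStart
#'   trialData
#' @return \code{nTrials}/\code{nSamples}: integer counts;
#'   \code{channelNames}: character; \code{trialLabels}: integer vector;
#'   \code{samplingRate}: Hz; \code{epochStart}: ms of the first sample;
#'   \code{trialData}: the trials x samples matrix of one channel.
NULL

#' @rdname TrialSet-accessors
#' @export
setMethod("nTrials", "TrialSet", function(x) nrow(x@data[[1]]))

#' @rdname TrialSet-accessors
#' @export
setMethod("nSamples", "TrialSet", function(x) ncol(x@data[[1]]))

#' @rdname TrialSet-accessors
#' @export
setMethod("channelNames", "TrialSet", function(x) names(x@data))

#' @rdname TrialSet-accessors
#' @export
setMethod("trialLabels", "TrialSet", function(x) x@labels)

#' @rdname TrialSet-accessors
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@fsHz)

#' @rdname TrialSet-accessors
#' @export
setMethod("epochStart", "TrialSet", function(x) x@t0Ms)

#' @rdname TrialSet-accessors
#' @export
setMethod("trialData", "TrialSet", function(x, channel) {
  if (is.character(channel) && !channel %in% names(x@data)) {
    stop("unknown channel '", channel, "'; available: ",
         paste(names(x@data), collapse = ", "))
  }
  x@data[[channel]]
})

#' @describeIn TrialSet-accessors subset trials: \code{x[i]} keeps trials
#'   \code{i} (every channel and the labels are subset consistently).
#' @param i trial indices (integer or logical).
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  new("TrialSet",
      data = lapply(x@data, function(m) m[i, , drop = FALSE]),
      labels = x@labels[i], fsHz = x@fsHz, t0Ms = x@t0Ms,
      provenance = x@provenance)
})

setMethod("show", "TrialSet", function(object) {
  lab <- table(object@labels)
  cat("TrialSet:", nTrials(object), "trials x", nSamples(object),
      "samples,", length(object@data), "channel(s)\n")
  cat("  channels:", paste(head(names(object@data), 8), collapse = ", "),
      if (length(object@data) > 8) "..." else "", "\n")
  cat("  fs:", object@fsHz, "Hz; epoch [", object@t0Ms, ",",
      object@t0Ms + 1000 * nSamples(object) / object@fsHz, ") ms\n")
  cat("  classes:", paste(sprintf("%s (n=%d)", names(lab), lab),
                          collapse = ", "), "\n")
})

#' Combine TrialSets as channels of one recording
#'
#' All inputs must share trial count, labels (trial-by-trial), sampling rate
#' and epoch start; their channels are concatenated into a single multichannel
#' [TrialSet-class]. Duplicate channel names are made unique.
#'
#' @param ... TrialSet objects.
#' @return a multichannel [TrialSet-class].
#' @export
bindChannels <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, is, logical(1), class2 = "TrialSet")))
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (nTrials(s) != nTrials(ref) || !identical(s@labels, ref@labels)) {
      stop("all TrialSets must share trials and labels")
    }
    if (s@fsHz != ref@fsHz || s@t0Ms != ref@t0Ms ||
        nSamples(s) != nSamples(ref)) {
      stop("all TrialSets must share sampling rate, epoch start and length")
    }
  }
  data <- do.call(c, lapply(sets, function(s) s@data))
  names(data) <- make.unique(names(data), sep = ".")
  new("TrialSet", data = data, labels = ref@labels, fsHz = ref@fsHz,
      t0Ms = ref@t0Ms, provenance = ref@provenance)
}
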