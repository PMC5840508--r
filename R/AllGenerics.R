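#' @rdname TrialSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("epochStart", function(x) standardGeneric("epochStart"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("trialData", function(x, channel) standardGeneric("trialData"))

#' @rdname DecodingResult-accessors
#' @export
setGeneric("performance", function(x) standardGeneric("performance"))

#' @rdname DecodingResult-accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname DecodingResult-accessors
#' @export
setGeneric("foldSelections", function(x) standardGeneric("foldSelections"))

#' @rdname DecodingResult-accessors
#' @export
setGeneric("coefficientIndex", function(x) standardGeneric("coefficientIndex"))

#' @rdname NullDistribution-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname NullDistribution-accessors
#' @export
setGeneric("nullPerformances", function(x) standardGeneric("nullPerformances"))
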