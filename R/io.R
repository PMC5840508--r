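## Plain-text epoch-matrix interchange format:
##   <dir>/<channel>.csv  headerless trials x samples matrix, one per channel
##   <dir>/labels.csv     one integer class label per line
##   <dir>/meta.json      fs_hz, t0_ms, channels (order contract), provenance
## Numbers are written with %.17g so a write/read round-trip is bit-exact.

#' Write a TrialSet to an epoch-matrix directory
#'
#' @param trials a [TrialSet-class].
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @seealso [readTrialSet()]
#' @export
writeTrialSet <- function(trials, path) {
  if (nTrials(trials) == 0) stop("refusing to write an empty TrialSet")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (ch in channelNames(trials)) {
    m <- trialData(trials, ch)
    lines <- vapply(seq_len(nrow(m)), function(i) {
      paste(sprintf("%.17g", m[i, ]), collapse = ",")
    }, character(1))
    writeLines(lines, file.path(path, paste0(ch, ".csv")))
  }
  writeLines(as.character(trialLabels(trials)), file.path(path, "labels.csv"))
  jsonlite::write_json(
    list(fs_hz = samplingRate(trials), t0_ms = epochStart(trials),
         channels = as.list(channelNames(trials)),
         provenance = trials@provenance),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a TrialSet from an epoch-matrix directory
#'
#' Validates shapes on the way in: every channel matrix named in
#' \code{meta.json} must exist, all channels must agree in trial and sample
#' counts, and \code{labels.csv} must have one integer per trial. Errors name
#' the offending file.
#'
#' @param path directory written by [writeTrialSet()] (or assembled by hand
#'   in the same dialect).
#' @return a validated [TrialSet-class]; channel order follows
#'   \code{meta.json}.
#' @export
readTrialSet <- function(path) {
  metaFile <- file.path(path, "meta.json")
  if (!file.exists(metaFile)) stop("missing meta.json in ", path)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  for (field in c("fs_hz", "t0_ms", "channels")) {
    if (is.null(meta[[field]])) {
      stop("meta.json is missing required field '", field, "'")
    }
  }
  channels <- as.character(meta$channels)

  data <- vector("list", length(channels))
  names(data) <- channels
  for (ch in channels) {
    f <- file.path(path, paste0(ch, ".csv"))
    if (!file.exists(f)) stop("missing channel file ", basename(f))
    m <- as.matrix(data.table::fread(f, header = FALSE, sep = ","))
    dimnames(m) <- NULL
    if (!is.numeric(m)) stop("non-numeric cells in ", basename(f))
    data[[ch]] <- m
  }
  dims <- vapply(data, dim, integer(2))
  if (length(channels) > 1 && any(dims != dims[, 1])) {
    stop("channel matrices disagree in shape (see ",
         paste0(channels[which(colSums(dims != dims[, 1]) > 0)[1]], ".csv"),
         ")")
  }

  labFile <- file.path(path, "labels.csv")
  if (!file.exists(labFile)) stop("missing labels.csv in ", path)
  labels <- suppressWarnings(as.integer(readLines(labFile)))
  if (anyNA(labels)) stop("non-integer entries in labels.csv")
  if (length(labels) != nrow(data[[1]])) {
    stop("labels.csv has ", length(labels), " lines but channels have ",
         nrow(data[[1]]), " trials")
  }

  prov <- meta$provenance
  new("TrialSet", data = data, labels = labels,
      fsHz = as.numeric(meta$fs_hz), t0Ms = as.numeric(meta$t0_ms),
      provenance = if (is.null(prov)) list() else as.list(prov))
}
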