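## Uniform-prior Gaussian naive Bayes and leave-one-out decoding.

#' Fit a uniform-prior Gaussian naive Bayes model
#'
#' One univariate Gaussian likelihood per (class, feature), with per-class
#' mean and variance. Class priors are uniform regardless of class counts.
#' Variances are floored at \code{1e-9} times the pooled (all-class) variance
#' of the feature; a feature that is constant across all training rows gets
#' unit variance (its likelihood is then identical across classes and does
#' not influence prediction).
#'
#' @param features n x p numeric matrix (or vector for p = 1).
#' @param labels class label per row; every class needs >= 2 rows.
#' @return an object of class \code{"naiveBayesModel"} with elements
#'   \code{classes}, \code{means} (classes x p), \code{vars} (classes x p).
#' @seealso [predictNaiveBayes()]
#' @export
fitNaiveBayes <- function(features, labels) {
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts < 2)) {
    stop("class ", paste(classes[counts < 2], collapse = ", "),
         " has fewer than 2 training trials")
  }
  model <- .fitNB(x, labels, classes)
  structure(model, class = "naiveBayesModel")
}

## internal fast path: no input checking (looDecode validates preconditions
## once up front)
.fitNB <- function(x, labels, classes) {
  g <- match(labels, classes)
  n <- tabulate(g, length(classes))
  sums <- rowsum(x, g)
  means <- sums / n
  sq <- rowsum(x * x, g)
  vars <- (sq - n * means^2) / (n - 1)
  pooledVar <- apply(x, 2, var)
  floorVar <- 1e-9 * pooledVar
  vars <- pmax(vars, rep(floorVar, each = length(classes)))
  vars[, pooledVar == 0] <- 1
  list(classes = classes, means = means, vars = vars)
}

#' Predict classes with a naive Bayes model
#'
#' Computes the per-class sum of Gaussian log-likelihoods over features (the
#' uniform prior adds a constant and is omitted), predicts the argmax class
#' — ties broken deterministically in favour of the first class in model
#' order — and returns posteriors normalised to sum to 1.
#'
#' @param model a model from [fitNaiveBayes()].
#' @param newdata numeric vector (one observation) or n x p matrix.
#' @return list with \code{class} (predicted label per observation) and
#'   \code{posterior} (n x classes matrix, rows summing to 1).
#' @export
predictNaiveBayes <- function(model, newdata) {
  x <- if (is.null(dim(newdata))) matrix(newdata, 1) else as.matrix(newdata)
  if (ncol(x) != ncol(model$means)) {
    stop("feature dimension (", ncol(x), ") does not match the model (",
         ncol(model$means), ")")
  }
  ll <- .nbLogLik(model, x)
  pred <- model$classes[max.col(ll, ties.method = "first")]
  ## normalised posteriors via log-sum-exp
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  list(class = pred, posterior = post)
}

.nbLogLik <- function(model, x) {
  nC <- length(model$classes)
  ll <- matrix(0, nrow(x), nC)
  for (c in seq_len(nC)) {
    mu <- model$means[c, ]
    v <- model$vars[c, ]
    centered <- sweep(x, 2, mu)
    ll[, c] <- -0.5 * sum(log(2 * pi * v)) -
      rowSums(sweep(centered^2, 2, 2 * v, "/"))
  }
  ll
}

## fold seed substream: independent, reproducible folds
.foldSeed <- function(seed, fold) {
  as.integer((as.numeric(seed) + 104729 * fold) %% 2147483647)
}

#' Leave-one-out wavelet-information decoding
#'
#' The full pipeline: every trial of every requested channel is Haar-
#' decomposed once; then, for each held-out trial, the per-coefficient mutual
#' information is re-estimated from bootstrap sub-ensemble averages of the
#' remaining trials only, the \code{nSelect} most informative coefficients
#' are selected from the pooled channels, a uniform-prior Gaussian naive
#' Bayes model is fit on the remaining trials' selected coefficients, and the
#' held-out trial is classified. The held-out trial influences neither
#' selection nor fitting. Each fold's bootstrap draws use an independent RNG
#' substream derived from \code{(seed, trial index)}, so single folds are
#' reproducible in isolation.
#'
#' @param trials a [TrialSet-class]; >= 2 classes, every class >= 3 trials.
#' @param channels channels to use (default all); with several channels the
#'   selection is pooled globally, so one channel may contribute all
#'   coefficients.
#' @param nSelect number of coefficients selected per fold.
#' @param nSubaverages,trialsPerAverage,quantBits sub-ensemble information
#'   estimation parameters (see [coefficientInformation()]).
#' @param nLevels wavelet decomposition depth.
#' @param seed master seed for the per-fold bootstrap substreams.
#' @param pad non-dyadic epoch handling, as in [coefficientInformation()].
#' @return a [DecodingResult-class]; performance is the proportion of trials
#'   correctly classified, and the per-fold selections are retained for
#'   [selectionRateMap()].
#' @examples
#' ts <- simulateTrialSet(simulationConfig(trialsPerClass = 8, fsHz = 64,
#'                                         epochMs = 500), seed = 1)
#' res <- looDecode(ts, nSelect = 10, nSubaverages = 20, seed = 1)
#' performance(res)
#' @export
looDecode <- function(trials, channels = channelNames(trials), nSelect = 25,
                      nSubaverages = 200, trialsPerAverage = 30,
                      quantBits = 2, nLevels = 5, seed = 1,
                      pad = c("error", "reflect")) {
  pad <- match.arg(pad)
  labels <- trialLabels(trials)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 3)) stop("every class needs at least 3 trials")

  dec <- .decomposeChannels(trials, channels, nLevels, pad)
  index <- dec$index
  bigW <- do.call(cbind, dec$coef)  # trials x (channels * coefficients)
  n <- nTrials(trials)

  selectable <- index$inSupport
  ## precomputed tie-break permutation: among equal info, coarser level,
  ## earlier support, earlier channel, lower id win
  tieOrder <- order(index$levelRank, index$supportStartMs, index$channelRank,
                    index$coeffId)

  pred <- integer(n)
  selections <- matrix(0L, n, nSelect)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    set.seed(.foldSeed(seed, i))
    idxByClass <- .drawClassIndices(labels, train, nSubaverages,
                                    trialsPerAverage)
    info <- unlist(lapply(dec$coef, .channelInfo, idxByClass = idxByClass,
                          nAverages = nSubaverages,
                          trialsPerAverage = trialsPerAverage,
                          quantBits = quantBits), use.names = FALSE)
    infoTie <- info[tieOrder]
    okTie <- selectable[tieOrder]
    sel <- tieOrder[okTie][order(-infoTie[okTie])[seq_len(nSelect)]]
    selections[i, ] <- sel

    model <- .fitNB(bigW[train, sel, drop = FALSE], labels[train], classes)
    ll <- .nbLogLik(model, bigW[i, sel, drop = FALSE])
    pred[i] <- classes[max.col(ll, ties.method = "first")]
  }

  .decodingResult(labels, pred, classes, selections, index,
                  method = "wavelet-information",
                  params = list(channels = channels, nSelect = nSelect,
                                nSubaverages = nSubaverages,
                                trialsPerAverage = trialsPerAverage,
                                quantBits = quantBits, nLevels = nLevels,
                                seed = seed, pad = pad))
}

.decodingResult <- function(labels, pred, classes, selections, index,
                            method, params) {
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  for (ci in seq_along(classes)) {
    rows <- labels == classes[ci]
    conf[ci, ] <- vapply(classes, function(cj) mean(pred[rows] == cj),
                         numeric(1))
  }
  new("DecodingResult",
      trueLabels = as.integer(labels), predictedLabels = as.integer(pred),
      performance = mean(pred == labels), confusion = conf,
      foldSelections = selections, index = index,
      method = method, params = params)
}

#' DecodingResult accessors
#'
#' @param x a [DecodingResult-class].
#' @name DecodingResult-accessors
#' @aliases performance confusionMatrix foldSelections coefficientIndex
#' @return \code{performance}: proportion correct; \code{confusionMatrix}:
#'   row-normalised matrix (rows = true class); \code{foldSelections}:
#'   folds x K matrix of selected global coefficient ids;
#'   \code{coefficientIndex}: the coefficient index data.frame.
NULL

#' @rdname DecodingResult-accessors
#' @export
setMethod("performance", "DecodingResult", function(x) x@performance)

#' @rdname DecodingResult-accessors
#' @export
setMethod("confusionMatrix", "DecodingResult", function(x) x@confusion)

#' @rdname DecodingResult-accessors
#' @export
setMethod("foldSelections", "DecodingResult", function(x) x@foldSelections)

#' @rdname DecodingResult-accessors
#' @export
setMethod("coefficientIndex", "DecodingResult", function(x) x@index)

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult (", object@method, ")\n", sep = "")
  cat("  trials:", length(object@trueLabels),
      " classes:", paste(rownames(object@confusion), collapse = ", "), "\n")
  cat("  performance:", sprintf("%.1f%%", 100 * object@performance), "\n")
  cat("  confusion (rows = true):\n")
  print(round(object@confusion, 3))
})
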