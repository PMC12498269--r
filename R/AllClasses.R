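#' @useDynLib neurovad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Multichannel raw neural recording
#'
#' Container for a continuous multichannel recording (samples x channels)
#' together with its sampling rate, channel labels, the grid each channel
#' belongs to (common average referencing is applied per grid), and the set
#' of channels marked bad.
#'
#' @slot samples numeric matrix, n_samples x n_channels.
#' @slot sampleRate sampling rate in Hz (1000 for the reference setup).
#' @slot channelIds character labels, one per column of \code{samples}.
#' @slot gridOfChannel integer grid index per channel.
#' @slot badChannels character subset of \code{channelIds} excluded from
#'   referencing and analysis.
#'
#' @export
setClass("RawRecording",
  representation(
    samples = "matrix",
    sampleRate = "numeric",
    channelIds = "character",
    gridOfChannel = "integer",
    badChannels = "character"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  nc <- ncol(object@samples)
  if (length(object@channelIds) != nc)
    msg <- c(msg, "channelIds length must equal ncol(samples)")
  if (anyDuplicated(object@channelIds))
    msg <- c(msg, "channelIds must be unique")
  if (length(object@gridOfChannel) != nc)
    msg <- c(msg, "gridOfChannel must cover all channels")
  if (!all(object@badChannels %in% object@channelIds))
    msg <- c(msg, "badChannels must be a subset of channelIds")
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param samples numeric matrix (n_samples x n_channels).
#' @param sampleRate sampling rate in Hz.
#' @param channelIds optional character labels (default \code{"ch1"...}).
#' @param gridOfChannel integer grid index per channel (default: all grid 1).
#' @param badChannels character vector of bad channel labels.
#' @return A \linkS4class{RawRecording}.
#' @export
RawRecording <- function(samples, sampleRate = 1000,
                         channelIds = NULL, gridOfChannel = NULL,
                         badChannels = character()) {
  samples <- as.matrix(samples)
  if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(ncol(samples)))
  if (is.null(gridOfChannel)) gridOfChannel <- rep(1L, ncol(samples))
  new("RawRecording", samples = samples, sampleRate = as.numeric(sampleRate),
      channelIds = as.character(channelIds),
      gridOfChannel = as.integer(gridOfChannel),
      badChannels = as.character(badChannels))
}

#' Frame-level feature sequence
#'
#' A T x D matrix of features computed on 50 ms windows advanced by 10 ms
#' (log high-gamma power per channel), optionally z-scored against baseline
#' statistics and optionally context-stacked (D = C * number of lags).
#'
#' @slot values numeric matrix, T x D.
#' @slot frameShift frame shift in ms (10).
#' @slot window analysis window length in ms (50).
#' @slot startTime time (s) of the first frame's window start.
#' @slot channelIds feature labels (length D).
#' @slot normalized logical; TRUE after z-scoring.
#' @slot stackLags integer lags (in frames) used for context stacking;
#'   length 0 when unstacked.
#'
#' @export
setClass("FrameSequence",
  representation(
    values = "matrix",
    frameShift = "numeric",
    window = "numeric",
    startTime = "numeric",
    channelIds = "character",
    normalized = "logical",
    stackLags = "integer"
  )
)

setValidity("FrameSequence", function(object) {
  msg <- character()
  if (length(object@channelIds) != ncol(object@values))
    msg <- c(msg, "channelIds length must equal ncol(values)")
  if (object@frameShift <= 0 || object@window <= 0)
    msg <- c(msg, "frameShift and window must be positive")
  if (length(object@stackLags) &&
      ncol(object@values) %% length(object@stackLags) != 0)
    msg <- c(msg, "stacked D must be a multiple of the number of lags")
  if (length(msg)) msg else TRUE
})

#' Construct a FrameSequence
#'
#' @param values numeric matrix, frames in rows.
#' @param frameShift frame shift in ms.
#' @param window window length in ms.
#' @param startTime start time (s) of the first window.
#' @param channelIds feature labels.
#' @param normalized logical z-scored flag.
#' @param stackLags integer stacking lags in frames (empty if unstacked).
#' @return A \linkS4class{FrameSequence}.
#' @export
FrameSequence <- function(values, frameShift = 10, window = 50,
                          startTime = 0, channelIds = NULL,
                          normalized = FALSE, stackLags = integer()) {
  values <- as.matrix(values)
  if (is.null(channelIds)) {
    channelIds <- colnames(values)
    if (is.null(channelIds)) channelIds <- paste0("f", seq_len(ncol(values)))
  }
  new("FrameSequence", values = values, frameShift = as.numeric(frameShift),
      window = as.numeric(window), startTime = as.numeric(startTime),
      channelIds = as.character(channelIds), normalized = normalized,
      stackLags = as.integer(stackLags))
}

#' Per-frame label sequence
#'
#' Integer labels at the feature frame rate: raw cluster IDs after TICC, or
#' binary speech/non-speech (0 = non-speech, 1 = speech) after class
#' inference.
#'
#' @slot labels integer vector, one label per frame.
#' @slot frameShift frame shift in ms (matches the source FrameSequence).
#' @slot startTime time (s) of the first frame.
#' @slot classes named character map from label value to class name.
#'
#' @export
setClass("LabelSequence",
  representation(
    labels = "integer",
    frameShift = "numeric",
    startTime = "numeric",
    classes = "character"
  )
)

setValidity("LabelSequence", function(object) {
  msg <- character()
  if (object@frameShift <= 0) msg <- c(msg, "frameShift must be positive")
  if (length(object@classes) && is.null(names(object@classes)))
    msg <- c(msg, "classes must be a named map label -> class name")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelSequence
#'
#' @param labels integer vector of per-frame labels.
#' @param frameShift frame shift in ms.
#' @param startTime time (s) of the first frame.
#' @param classes named character map label value -> class name.
#' @return A \linkS4class{LabelSequence}.
#' @export
LabelSequence <- function(labels, frameShift = 10, startTime = 0,
                          classes = c(`0` = "non-speech", `1` = "speech")) {
  new("LabelSequence", labels = as.integer(labels),
      frameShift = as.numeric(frameShift), startTime = as.numeric(startTime),
      classes = classes)
}

#' Gaussian Markov random field cluster
#'
#' One TICC cluster: a Gaussian over the (possibly multi-layer) embedded
#' observation with mean \code{mu} and a symmetric positive-definite
#' precision matrix that is block-Toeplitz in w x w sub-blocks of size C.
#'
#' @slot mean numeric mean vector (length w*C).
#' @slot precision precision (inverse covariance) matrix, w*C x w*C.
#' @slot logDet cached log-determinant of the precision.
#' @slot nAssigned number of frames assigned at the last update.
#' @slot nLayers number of Toeplitz layers w.
#' @slot nChannels base feature dimension C.
#'
#' @export
setClass("MRFCluster",
  representation(
    mean = "numeric",
    precision = "matrix",
    logDet = "numeric",
    nAssigned = "integer",
    nLayers = "integer",
    nChannels = "integer"
  )
)

setValidity("MRFCluster", function(object) {
  msg <- character()
  d <- length(object@mean)
  if (!all(dim(object@precision) == c(d, d)))
    msg <- c(msg, "precision must be square with dimension length(mean)")
  if (d != object@nLayers * object@nChannels)
    msg <- c(msg, "length(mean) must equal nLayers * nChannels")
  if (d > 0 && max(abs(object@precision - t(object@precision))) > 1e-8)
    msg <- c(msg, "precision must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Fitted TICC model
#'
#' K Markov-random-field clusters plus the hyperparameters used to fit them,
#' the per-iteration objective trace, and convergence information.
#'
#' @slot clusters list of \linkS4class{MRFCluster}.
#' @slot hyper the \code{ticcHyperparams} list used for fitting.
#' @slot objectiveTrace numeric, objective value after each M-step.
#' @slot rescueIterations iterations whose assignment came from the
#'   empty-cluster restart heuristic; the objective may rise across such a
#'   restart, and is non-increasing everywhere else.
#' @slot converged logical: TRUE if the assignment became stationary.
#' @slot nIter number of EM iterations run.
#'
#' @export
setClass("TICCModel",
  representation(
    clusters = "list",
    hyper = "list",
    objectiveTrace = "numeric",
    rescueIterations = "integer",
    converged = "logical",
    nIter = "integer"
  )
)

setValidity("TICCModel", function(object) {
  if (!all(vapply(object@clusters, is, logical(1), "MRFCluster")))
    return("clusters must all be MRFCluster objects")
  TRUE
})

#' Ground truth for a synthetic session
#'
#' Frame-level reference voice-activity labels and the trial table they were
#' generated from (cue onsets and frame-quantized speech intervals).
#'
#' @slot vadLabels binary \linkS4class{LabelSequence} at 10 ms frames.
#' @slot trialTable data.frame with columns \code{trial}, \code{wordId},
#'   \code{cueOnset}, \code{speechOnset}, \code{speechOffset} (seconds).
#'
#' @export
setClass("GroundTruth",
  representation(vadLabels = "LabelSequence", trialTable = "data.frame")
)

setValidity("GroundTruth", function(object) {
  need <- c("trial", "wordId", "cueOnset", "speechOnset", "speechOffset")
  if (!all(need %in% names(object@trialTable)))
    return(paste("trialTable must have columns:", paste(need, collapse = ", ")))
  tt <- object@trialTable
  if (nrow(tt) && any(tt$speechOffset < tt$speechOnset))
    return("speech intervals must have non-negative duration")
  TRUE
})

#' Evaluation report
#'
#' Per-trial alignment errors and summary detection metrics, optionally per
#' cross-validation fold.
#'
#' @slot trialErrors data.frame with one row per scored trial (columns
#'   \code{fold}, \code{day}, \code{trial}, \code{errorMs},
#'   \code{majorityDetected}, \code{notDetected}).
#' @slot detectionProbability frame-level speech detection probability.
#' @slot falseAlarmProbability frame-level false alarm probability.
#' @slot majorityDetectionRate fraction of trials with >50% of reference
#'   speech frames predicted as speech.
#' @slot nNotDetected trials with zero reference speech frames detected.
#' @slot nErrorAboveMeanDuration trials whose alignment error exceeds the
#'   mean reference speech duration.
#' @slot perFold data.frame of per-fold summaries (may have zero rows).
#'
#' @export
setClass("EvalReport",
  representation(
    trialErrors = "data.frame",
    detectionProbability = "numeric",
    falseAlarmProbability = "numeric",
    majorityDetectionRate = "numeric",
    nNotDetected = "integer",
    nErrorAboveMeanDuration = "integer",
    perFold = "data.frame"
  )
)

setValidity("EvalReport", function(object) {
  pr <- c(object@detectionProbability, object@falseAlarmProbability,
          object@majorityDetectionRate)
  pr <- pr[!is.na(pr)]
  if (length(pr) && (any(pr < 0) || any(pr > 1)))
    return("probabilities must lie in [0, 1]")
  TRUE
})
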