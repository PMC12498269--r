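# Accessor generics and show methods. Slot access stays internal; user code
# goes through these.

#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @rdname accessors
#' @export
setGeneric("frameShift", function(x) standardGeneric("frameShift"))

#' @rdname accessors
#' @export
setGeneric("frameValues", function(x) standardGeneric("frameValues"))

#' @rdname accessors
#' @export
setGeneric("labels01", function(x) standardGeneric("labels01"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("precisionMatrix", function(x) standardGeneric("precisionMatrix"))

#' @rdname accessors
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))

#' @rdname accessors
#' @export
setGeneric("vadLabels", function(x) standardGeneric("vadLabels"))

#' @rdname accessors
#' @export
setGeneric("trialErrors", function(x) standardGeneric("trialErrors"))

#' Accessors for neurovad classes
#'
#' @name accessors
#' @rdname accessors
#' @aliases sampleRate channelIds frameShift frameValues labels01 nFrames
#'   clusters precisionMatrix trialTable vadLabels trialErrors
NULL

#' @rdname accessors
#' @export
setMethod("sampleRate", "RawRecording", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("channelIds", "RawRecording", function(x) x@channelIds)

#' @rdname accessors
#' @export
setMethod("channelIds", "FrameSequence", function(x) x@channelIds)

#' @rdname accessors
#' @export
setMethod("frameShift", "FrameSequence", function(x) x@frameShift)

#' @rdname accessors
#' @export
setMethod("frameShift", "LabelSequence", function(x) x@frameShift)

#' @rdname accessors
#' @export
setMethod("frameValues", "FrameSequence", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("labels01", "LabelSequence", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSequence", function(x) nrow(x@values))

#' @rdname accessors
#' @export
setMethod("nFrames", "LabelSequence", function(x) length(x@labels))

#' @rdname accessors
#' @export
setMethod("clusters", "TICCModel", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("precisionMatrix", "MRFCluster", function(x) x@precision)

#' @rdname accessors
#' @export
setMethod("trialTable", "GroundTruth", function(x) x@trialTable)

#' @rdname accessors
#' @export
setMethod("vadLabels", "GroundTruth", function(x) x@vadLabels)

#' @rdname accessors
#' @export
setMethod("trialErrors", "EvalReport", function(x) x@trialErrors)

#' Raw sample matrix of a recording
#' @param x a \linkS4class{RawRecording}.
#' @return numeric matrix, samples x channels.
#' @export
rawSamples <- function(x) {
  stopifnot(is(x, "RawRecording"))
  x@samples
}

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(object@samples), ncol(object@samples), object@sampleRate,
              nrow(object@samples) / object@sampleRate))
  cat(sprintf("  grids: %s; bad channels: %s\n",
              paste(sort(unique(object@gridOfChannel)), collapse = ","),
              if (length(object@badChannels))
                paste(object@badChannels, collapse = ",") else "none"))
})

setMethod("show", "FrameSequence", function(object) {
  cat(sprintf(
    "FrameSequence: %d frames x %d features (%g ms window / %g ms shift)\n",
    nrow(object@values), ncol(object@values), object@window,
    object@frameShift))
  cat(sprintf("  normalized: %s; stacked lags: %s\n", object@normalized,
              if (length(object@stackLags))
                paste(object@stackLags, collapse = ",") else "none"))
})

setMethod("show", "LabelSequence", function(object) {
  tab <- table(object@labels)
  cat(sprintf("LabelSequence: %d frames @ %g ms\n",
              length(object@labels), object@frameShift))
  if (length(tab)) {
    nm <- names(tab)
    cls <- object@classes[nm]
    cls[is.na(cls)] <- nm[is.na(cls)]
    cat("  ", paste(sprintf("%s (%s): %d", nm, cls, as.integer(tab)),
                    collapse = "; "), "\n")
  }
})

setMethod("show", "MRFCluster", function(object) {
  d <- length(object@mean)
  off <- object@precision
  diag(off) <- 0
  cat(sprintf(
    "MRFCluster: %d x %d precision (w = %d layers, C = %d), %d frames assigned\n",
    d, d, object@nLayers, object@nChannels, object@nAssigned))
  cat(sprintf("  off-diagonal density: %.3f; log det: %.3f\n",
              if (d > 1) mean(off[row(off) != col(off)] != 0) else 0,
              object@logDet))
})

setMethod("show", "TICCModel", function(object) {
  cat(sprintf("TICCModel: K = %d clusters, %d iterations, converged: %s\n",
              length(object@clusters), object@nIter, object@converged))
  cat(sprintf("  beta = %g, lambda = %g, layers = %d, dilation = %d frames\n",
              object@hyper$beta, object@hyper$lam, object@hyper$nLayers,
              object@hyper$dilationFrames))
  if (length(object@objectiveTrace))
    cat(sprintf("  objective: %.4f -> %.4f\n",
                object@objectiveTrace[1],
                object@objectiveTrace[length(object@objectiveTrace)]))
  for (k in seq_along(object@clusters))
    cat(sprintf("  cluster %d: %d frames\n", k - 1L,
                object@clusters[[k]]@nAssigned))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d trials, %d label frames (%.1f%% speech)\n",
              nrow(object@trialTable), length(object@vadLabels@labels),
              100 * mean(object@vadLabels@labels == 1L)))
})

setMethod("show", "EvalReport", function(object) {
  te <- object@trialErrors
  cat(sprintf("EvalReport: %d trials\n", nrow(te)))
  if (nrow(te)) {
    q <- stats::quantile(te$errorMs, c(0.25, 0.5, 0.75), na.rm = TRUE)
    cat(sprintf("  alignment error (ms): median %.0f [Q1 %.0f, Q3 %.0f]\n",
                q[2], q[1], q[3]))
  }
  cat(sprintf(
    "  detection %.3f | false alarm %.3f | majority detection %.3f\n",
    object@detectionProbability, object@falseAlarmProbability,
    object@majorityDetectionRate))
  cat(sprintf("  not detected: %d; error > mean speech duration: %d\n",
              object@nNotDetected, object@nErrorAboveMeanDuration))
})
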