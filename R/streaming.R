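# Real-time pipeline: a linear directed acyclic graph of processing nodes
# (ingest -> CAR -> bandpass -> notch -> framer -> z-score -> classifier ->
# emitter -> log), each with explicit state, contractually frame-identical
# to the offline path: the filters carry per-channel SOS delay lines, the
# framer buffers raw samples with no look-ahead, and the classifier node
# folds the same single-frame forward pass as predictOffline.

#' Streaming preprocessing configuration
#'
#' @param sampleRate raw sampling rate, Hz.
#' @param channelIds labels of the incoming raw channels.
#' @param gridOfChannel grid index per incoming channel.
#' @param badChannels channels dropped before referencing.
#' @param selectedChannels channels kept after referencing, in order; must
#'   match the classifier input dimension.
#' @param baselineStats \linkS4class{BaselineStats} for z-scoring
#'   (required).
#' @param window,frameShift framing in ms.
#' @param logFile optional path; the logging node appends one line per
#'   emitted event.
#' @return list of class \code{"streamConfig"}.
#' @export
streamConfig <- function(sampleRate = 1000, channelIds, gridOfChannel = NULL,
                         badChannels = character(), selectedChannels = NULL,
                         baselineStats = NULL, window = 50, frameShift = 10,
                         logFile = NULL) {
  if (is.null(gridOfChannel)) gridOfChannel <- rep(1L, length(channelIds))
  cfg <- list(sampleRate = sampleRate, channelIds = as.character(channelIds),
              gridOfChannel = as.integer(gridOfChannel),
              badChannels = as.character(badChannels),
              selectedChannels = selectedChannels,
              baselineStats = baselineStats, window = window,
              frameShift = frameShift, logFile = logFile)
  class(cfg) <- "streamConfig"
  cfg
}

#' Assemble the streaming pipeline
#'
#' Builds the node graph with fresh per-node state. Requires baseline
#' statistics at build time (a real-time system cannot z-score without its
#' calibration segment). Two pipelines built from the same model hold
#' independent state.
#'
#' @param model a trained \linkS4class{ClassifierModel}.
#' @param config a \code{\link{streamConfig}}.
#' @return pipeline object for \code{\link{pushSamples}}.
#' @export
buildPipeline <- function(model, config) {
  stopifnot(is(model, "ClassifierModel"), inherits(config, "streamConfig"))
  if (is.null(config$baselineStats))
    stop("baseline statistics are required to build the pipeline")
  stopifnot(is(config$baselineStats, "BaselineStats"))
  keep <- !(config$channelIds %in% config$badChannels)
  ids <- config$channelIds[keep]
  sel <- config$selectedChannels %||% ids
  if (any(!sel %in% ids))
    stop("selected channels unavailable after dropping bad channels")
  if (length(sel) != model@inputSpec$C)
    stop("selected channel count does not match the classifier input")
  if (length(config$baselineStats@mean) != model@inputSpec$C)
    stop("baseline statistics do not match the classifier input")
  filters <- designHGFilters(config$sampleRate)
  fs <- config$sampleRate
  ws <- as.integer(round(config$window * fs / 1000))
  ss <- as.integer(round(config$frameShift * fs / 1000))
  pl <- new.env(parent = emptyenv())
  pl$model <- model
  pl$config <- config
  pl$keep <- keep
  pl$selIdx <- match(sel, ids)
  pl$grids <- config$gridOfChannel[keep]
  pl$filters <- filters
  pl$ws <- ws; pl$ss <- ss
  pl$bpState <- sosInitState(filters$bandpass, length(ids))
  pl$nsState <- sosInitState(filters$bandstop, length(ids))
  pl$frameBuf <- matrix(0, 0, length(ids))
  pl$clsState <- freshState(model)
  pl$frameIndex <- 0L
  pl$nodeNames <- c("ingest", "car", "bandpass", "notch", "framer",
                    "zscore", "classifier", "emit", "log")
  class(pl) <- "nvadPipeline"
  pl
}

#' Node order of a pipeline
#' @param pipeline a pipeline from \code{\link{buildPipeline}}.
#' @return character vector of node names in processing order.
#' @export
pipelineNodes <- function(pipeline) {
  stopifnot(inherits(pipeline, "nvadPipeline"))
  pipeline$nodeNames
}

#' Push a chunk of raw samples through the pipeline
#'
#' Emits one event per completed 10 ms frame (the first after the initial
#' 50 ms window has filled). The concatenated event classes are invariant
#' to how the sample stream is chunked, and equal the offline
#' \code{\link{predictOffline}} classes on the same signal. Per-node
#' latencies are measured and reported, never asserted.
#'
#' @param pipeline a pipeline from \code{\link{buildPipeline}}.
#' @param chunk numeric matrix (samples x raw channels); a vector is taken
#'   as a single multichannel sample.
#' @return data.frame of events: \code{frameIndex}, \code{time} (s, frame
#'   window start), \code{class} (0/1), and per-node latency columns (ms).
#' @export
pushSamples <- function(pipeline, chunk) {
  stopifnot(inherits(pipeline, "nvadPipeline"))
  if (is.null(dim(chunk))) chunk <- matrix(chunk, nrow = 1)
  if (ncol(chunk) != length(pipeline$config$channelIds))
    stop("chunk has ", ncol(chunk), " channels, expected ",
         length(pipeline$config$channelIds))
  lat <- c(ingest = 0, car = 0, bandpass = 0, notch = 0, framer = 0,
           zscore = 0, classifier = 0, emit = 0, log = 0)
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  x <- chunk[, pipeline$keep, drop = FALSE]
  lat["ingest"] <- tic() - t0
  # common average referencing per grid (stateless per sample)
  t0 <- tic()
  for (g in unique(pipeline$grids)) {
    cols <- which(pipeline$grids == g)
    m <- rowMeans(x[, cols, drop = FALSE])
    x[, cols] <- x[, cols, drop = FALSE] - m
  }
  lat["car"] <- tic() - t0
  t0 <- tic()
  r <- sosApply(x, pipeline$filters$bandpass, pipeline$bpState)
  pipeline$bpState <- r$zi
  lat["bandpass"] <- tic() - t0
  t0 <- tic()
  r <- sosApply(r$y, pipeline$filters$bandstop, pipeline$nsState)
  pipeline$nsState <- r$zi
  lat["notch"] <- tic() - t0
  # framer: emit every completed window, advancing by the frame shift
  t0 <- tic()
  buf <- rbind(pipeline$frameBuf, r$y)
  frames <- list()
  while (nrow(buf) >= pipeline$ws) {
    frames[[length(frames) + 1L]] <-
      windowLogPower(buf[seq_len(pipeline$ws), , drop = FALSE])
    buf <- buf[-seq_len(pipeline$ss), , drop = FALSE]
  }
  pipeline$frameBuf <- buf
  lat["framer"] <- tic() - t0
  if (!length(frames)) {
    return(data.frame(frameIndex = integer(0), time = numeric(0),
                      class = integer(0)))
  }
  st <- pipeline$config$baselineStats
  events <- data.frame(frameIndex = integer(length(frames)),
                       time = numeric(length(frames)),
                       class = integer(length(frames)))
  for (i in seq_along(frames)) {
    t0 <- tic()
    feat <- (frames[[i]][pipeline$selIdx] - st@mean) / st@sd
    lat["zscore"] <- lat["zscore"] + tic() - t0
    t0 <- tic()
    pr <- predictStep(pipeline$model, feat, pipeline$clsState)
    pipeline$clsState <- pr$state
    lat["classifier"] <- lat["classifier"] + tic() - t0
    t0 <- tic()
    events$frameIndex[i] <- pipeline$frameIndex
    events$time[i] <- pipeline$frameIndex * pipeline$config$frameShift / 1000
    events$class[i] <- pr$class
    pipeline$frameIndex <- pipeline$frameIndex + 1L
    lat["emit"] <- lat["emit"] + tic() - t0
  }
  t0 <- tic()
  if (!is.null(pipeline$config$logFile)) {
    cat(sprintf("%d\t%.3f\t%d\n", events$frameIndex, events$time,
                events$class),
        file = pipeline$config$logFile, append = TRUE, sep = "")
  }
  lat["log"] <- tic() - t0
  for (nm in names(lat)) events[[paste0("lat_", nm)]] <- 1000 * lat[[nm]]
  events
}

#' Reconstruct the event sequence from a pipeline log
#'
#' @param path log file written by the pipeline's logging node.
#' @return data.frame with \code{frameIndex}, \code{time}, \code{class}.
#' @export
replayLog <- function(path) {
  lines <- readLines(path)
  out <- data.frame(frameIndex = integer(length(lines)),
                    time = numeric(length(lines)),
                    class = integer(length(lines)))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != 3 || anyNA(vals) || !(vals[3] %in% c(0, 1)))
      stop("corrupt log at line ", i, ": '", lines[i], "'")
    out$frameIndex[i] <- as.integer(vals[1])
    out$time[i] <- vals[2]
    out$class[i] <- as.integer(vals[3])
  }
  if (nrow(out) > 1 && any(diff(out$frameIndex) <= 0))
    stop("frame indices are not strictly increasing")
  out
}

#' Initialize a log file for the pipeline's logging node
#' @param path file path (truncated).
#' @return the path, invisibly.
#' @export
initStreamLog <- function(path) {
  cat("", file = path)
  invisible(path)
}
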