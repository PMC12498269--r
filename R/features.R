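#' Baseline normalization statistics
#'
#' Per-feature mean and standard deviation estimated from a calibration
#' (syllable-task) segment, used to z-score a day's features.
#'
#' @slot mean per-feature mean.
#' @slot sd per-feature standard deviation (population convention, floored).
#' @slot source identifier of the day/segment the statistics came from.
#' @export
setClass("BaselineStats",
  representation(mean = "numeric", sd = "numeric", source = "character")
)

setValidity("BaselineStats", function(object) {
  if (length(object@mean) != length(object@sd))
    return("mean and sd must have equal length")
  if (any(object@sd <= 0)) return("sd must be positive (floored)")
  TRUE
})

#' Common average referencing and channel selection
#'
#' Drops channels marked bad, subtracts from every remaining channel the
#' per-sample mean of the retained channels of its grid (common average
#' referencing, applied to each grid independently), then keeps only
#' \code{selectedChannels} in the given order.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param selectedChannels character vector of channels to retain (default:
#'   all non-bad channels). Selecting a bad channel is an error.
#' @return A referenced \linkS4class{RawRecording} with the selected
#'   channels only.
#' @export
preprocessRaw <- function(rec, selectedChannels = NULL) {
  stopifnot(is(rec, "RawRecording"))
  keep <- !(rec@channelIds %in% rec@badChannels)
  ids <- rec@channelIds[keep]
  grids <- rec@gridOfChannel[keep]
  x <- rec@samples[, keep, drop = FALSE]
  for (g in unique(grids)) {
    cols <- which(grids == g)
    m <- rowMeans(x[, cols, drop = FALSE])
    x[, cols] <- x[, cols, drop = FALSE] - m
  }
  if (is.null(selectedChannels)) selectedChannels <- ids
  if (any(selectedChannels %in% rec@badChannels))
    stop("selected channels marked bad: ",
         paste(intersect(selectedChannels, rec@badChannels), collapse = ", "))
  idx <- match(selectedChannels, ids)
  if (anyNA(idx))
    stop("unknown channels: ",
         paste(selectedChannels[is.na(idx)], collapse = ", "))
  RawRecording(x[, idx, drop = FALSE], sampleRate = rec@sampleRate,
               channelIds = ids[idx], gridOfChannel = grids[idx])
}

#' Log high-gamma power features
#'
#' Per channel: causal 4th-order Butterworth band-pass (70-170 Hz), causal
#' 4th-order Butterworth band-stop (118-122 Hz, first line-noise harmonic),
#' then the log mean squared amplitude of 50 ms windows advanced by 10 ms.
#' All filtering is strictly forward (no zero-phase pass), so the offline
#' features equal the streaming ones frame for frame.
#'
#' Frame \code{i} (0-based) covers samples \code{[i*shift, i*shift+window)};
#' a frame exists once its last sample does, giving
#' \code{T = floor((n - window) / shift) + 1} frames.
#'
#' @param rec a preprocessed \linkS4class{RawRecording}.
#' @param window window length in ms (50).
#' @param shift frame shift in ms (10).
#' @param filters SOS filter cascades from \code{\link{designHGFilters}}.
#' @param eps floor inside the log for silent windows.
#' @return A \linkS4class{FrameSequence} (unnormalized, unstacked). A signal
#'   shorter than one window yields an empty sequence.
#' @export
extractHGPower <- function(rec, window = 50, shift = 10,
                           filters = designHGFilters(sampleRate(rec)),
                           eps = 1e-10) {
  stopifnot(is(rec, "RawRecording"))
  fs <- rec@sampleRate
  ws <- as.integer(round(window * fs / 1000))
  ss <- as.integer(round(shift * fs / 1000))
  x <- sosApply(rec@samples, filters$bandpass)$y
  x <- sosApply(x, filters$bandstop)$y
  T <- frameCount(nrow(x), ws, ss)
  vals <- matrix(0, T, ncol(x))
  for (i in seq_len(T)) {
    s0 <- (i - 1L) * ss
    vals[i, ] <- windowLogPower(x[(s0 + 1L):(s0 + ws), , drop = FALSE], eps)
  }
  FrameSequence(vals, frameShift = shift, window = window, startTime = 0,
                channelIds = rec@channelIds, normalized = FALSE)
}

#' Fit baseline z-scoring statistics
#'
#' Per-feature mean and population standard deviation of a calibration
#' segment. Standard deviations below \code{sdFloor} are floored with a
#' warning (degenerate constant features).
#'
#' @param baselineFrames a \linkS4class{FrameSequence} with at least 2 frames.
#' @param source day identifier carried along for provenance.
#' @param sdFloor minimum admissible standard deviation.
#' @return A \linkS4class{BaselineStats}.
#' @export
fitBaselineStats <- function(baselineFrames, source = "baseline",
                             sdFloor = 1e-6) {
  stopifnot(is(baselineFrames, "FrameSequence"))
  x <- baselineFrames@values
  if (nrow(x) < 2) stop("baseline must contain at least 2 frames")
  mu <- colMeans(x)
  # population convention: z-scoring the baseline itself gives variance 1
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sdv < sdFloor)) {
    warning(sum(sdv < sdFloor), " feature(s) with (near-)zero variance; sd ",
            "floored at ", sdFloor)
    sdv <- pmax(sdv, sdFloor)
  }
  new("BaselineStats", mean = mu, sd = sdv, source = as.character(source))
}

#' Apply z-score normalization
#'
#' @param frames a \linkS4class{FrameSequence}.
#' @param stats a \linkS4class{BaselineStats} with matching dimension.
#' @return The normalized \linkS4class{FrameSequence}.
#' @export
applyZscore <- function(frames, stats) {
  stopifnot(is(frames, "FrameSequence"), is(stats, "BaselineStats"))
  if (ncol(frames@values) != length(stats@mean))
    stop("feature dimension does not match baseline statistics")
  v <- sweep(sweep(frames@values, 2, stats@mean), 2, stats@sd, "/")
  FrameSequence(v, frameShift = frames@frameShift, window = frames@window,
                startTime = frames@startTime, channelIds = frames@channelIds,
                normalized = TRUE, stackLags = frames@stackLags)
}

#' Context stacking
#'
#' Augments each frame with past frames at the given lags: row \code{t}
#' becomes the concatenation of rows \code{t - lag} for each lag, zero-filled
#' where \code{t - lag < 0}. The default lags (0, 5, ..., 30 frames at a
#' 10 ms shift) reproduce the non-overlapping 7-frame stacking covering 0 to
#' -300 ms used for classifiers without temporal memory.
#'
#' @param frames a \linkS4class{FrameSequence}.
#' @param lagsFrames non-negative integer lags in frames, sorted ascending,
#'   first element 0.
#' @return A stacked \linkS4class{FrameSequence} with D multiplied by the
#'   number of lags.
#' @export
stackContext <- function(frames, lagsFrames = seq(0L, 30L, by = 5L)) {
  stopifnot(is(frames, "FrameSequence"))
  lagsFrames <- as.integer(lagsFrames)
  if (length(lagsFrames) == 0 || lagsFrames[1] != 0L ||
      is.unsorted(lagsFrames, strictly = TRUE) || any(lagsFrames < 0L))
    stop("lags must be sorted ascending, non-negative, starting at 0")
  x <- frames@values
  T <- nrow(x); C <- ncol(x)
  out <- matrix(0, T, C * length(lagsFrames))
  for (j in seq_along(lagsFrames)) {
    lag <- lagsFrames[j]
    cols <- ((j - 1L) * C + 1L):(j * C)
    if (lag < T)
      out[(lag + 1L):T, cols] <- x[seq_len(T - lag), , drop = FALSE]
  }
  ids <- as.vector(vapply(lagsFrames, function(l)
    paste0(frames@channelIds, "_lag", l), character(C)))
  FrameSequence(out, frameShift = frames@frameShift, window = frames@window,
                startTime = frames@startTime, channelIds = ids,
                normalized = frames@normalized, stackLags = lagsFrames)
}
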