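#' Run-length segments of a label sequence
#'
#' @param labels a \linkS4class{LabelSequence}.
#' @return data.frame with columns \code{start}, \code{end} (half-open,
#'   0-based frames) and \code{label}, tiling \code{[0, T)} exactly.
#' @export
labelsToSegments <- function(labels) {
  stopifnot(is(labels, "LabelSequence"))
  l <- labels@labels
  if (!length(l))
    return(data.frame(start = integer(), end = integer(), label = integer()))
  r <- rle(l)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths, end = ends, label = r$values)
}

#' Label sequence from segments
#'
#' Inverse of \code{\link{labelsToSegments}}: segments must be contiguous,
#' non-overlapping and tile \code{[0, T)}.
#'
#' @param segs data.frame with \code{start}, \code{end}, \code{label}.
#' @param T total number of frames.
#' @param frameShift frame shift in ms.
#' @param startTime start time in s.
#' @param classes class map for the result.
#' @return A \linkS4class{LabelSequence}.
#' @export
segmentsToLabels <- function(segs, T, frameShift = 10, startTime = 0,
                             classes = c(`0` = "non-speech", `1` = "speech")) {
  T <- as.integer(T)
  if (nrow(segs) == 0) {
    if (T != 0) stop("segments do not tile [0, T)")
    return(LabelSequence(integer(0), frameShift, startTime, classes))
  }
  segs <- segs[order(segs$start), , drop = FALSE]
  if (segs$start[1] != 0L || segs$end[nrow(segs)] != T ||
      (nrow(segs) > 1 && any(segs$start[-1] != segs$end[-nrow(segs)])))
    stop("segments must tile [0, T) without gaps or overlaps")
  lab <- integer(T)
  for (i in seq_len(nrow(segs)))
    lab[(segs$start[i] + 1L):segs$end[i]] <- segs$label[i]
  LabelSequence(lab, frameShift, startTime, classes)
}

#' Infer speech/non-speech cluster classes from assignment durations
#'
#' In the cued single-word design the majority of session time carries no
#' speech, so of two clusters the one with the smaller total assigned
#' duration is taken as speech. The fraction of total time assigned to
#' speech is attached as attribute \code{"speechFraction"} (diagnostic).
#'
#' @param clusterLabels a \linkS4class{LabelSequence} of cluster IDs (K = 2
#'   expected).
#' @param rule \code{"total"} (default; total assigned duration) or
#'   \code{"meanRun"} (mean run length) as the measure of cluster length.
#' @return named character map cluster ID -> \code{"speech"} /
#'   \code{"non-speech"}.
#' @export
inferClassMap <- function(clusterLabels, rule = c("total", "meanRun")) {
  stopifnot(is(clusterLabels, "LabelSequence"))
  rule <- match.arg(rule)
  l <- clusterLabels@labels
  ids <- sort(unique(l))
  if (length(ids) == 1) {
    warning("only one cluster present; mapping it to non-speech")
    map <- setNames("non-speech", ids)
    attr(map, "speechFraction") <- 0
    return(map)
  }
  if (length(ids) != 2)
    stop("class inference expects K = 2 cluster assignments")
  meas <- if (rule == "total") {
    vapply(ids, function(k) sum(l == k), numeric(1))
  } else {
    r <- rle(l)
    vapply(ids, function(k) mean(r$lengths[r$values == k]), numeric(1))
  }
  if (meas[1] == meas[2]) {
    warning("exact tie in cluster durations; lower cluster index -> speech")
    speech <- ids[1]
  } else speech <- ids[which.min(meas)]
  map <- setNames(ifelse(ids == speech, "speech", "non-speech"), ids)
  attr(map, "speechFraction") <- sum(l == speech) / length(l)
  map
}

#' Relabel cluster IDs to binary speech labels
#'
#' @param clusterLabels a \linkS4class{LabelSequence} of cluster IDs.
#' @param map named map cluster ID -> \code{"speech"}/\code{"non-speech"}
#'   (from \code{\link{inferClassMap}}) covering all labels present.
#' @return binary \linkS4class{LabelSequence} (1 = speech).
#' @export
relabel <- function(clusterLabels, map) {
  stopifnot(is(clusterLabels, "LabelSequence"))
  l <- clusterLabels@labels
  present <- unique(l)
  if (!all(present %in% as.integer(names(map))))
    stop("unmapped cluster labels: ",
         paste(setdiff(present, as.integer(names(map))), collapse = ", "))
  bin <- as.integer(map[as.character(l)] == "speech")
  LabelSequence(bin, frameShift = clusterLabels@frameShift,
                startTime = clusterLabels@startTime)
}
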