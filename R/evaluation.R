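#' Alignment error between two binary label sequences
#'
#' 10 ms times the Levenshtein distance between the predicted and target
#' frame-label strings: every replace, insert and delete operation costs one
#' 10 ms frame, so the total is a timing error in milliseconds that also
#' accounts for temporal shifts (unlike plain accuracy).
#'
#' @param pred,target binary \linkS4class{LabelSequence}s with equal frame
#'   shift (lengths may differ).
#' @return alignment error in ms.
#' @export
alignmentError <- function(pred, target) {
  stopifnot(is(pred, "LabelSequence"), is(target, "LabelSequence"))
  checkBinaryLabels(pred@labels, "pred")
  checkBinaryLabels(target@labels, "target")
  if (pred@frameShift != target@frameShift)
    stop("frame shifts differ")
  pred@frameShift * levenshtein_cpp(pred@labels, target@labels)
}

#' Frame-level detection and false-alarm probabilities
#'
#' Detection: probability that a 10 ms frame containing speech is classified
#' as speech (TP / (TP + FN)). False alarm: probability that a non-speech
#' frame is classified as speech (FP / (FP + TN)). An empty denominator is
#' reported as NA, not 0.
#'
#' @param pred,target binary \linkS4class{LabelSequence}s of equal length.
#' @return named numeric: \code{detection}, \code{falseAlarm}.
#' @export
frameRates <- function(pred, target) {
  stopifnot(is(pred, "LabelSequence"), is(target, "LabelSequence"))
  checkBinaryLabels(pred@labels, "pred")
  checkBinaryLabels(target@labels, "target")
  p <- pred@labels; t <- target@labels
  if (length(p) != length(t)) stop("length mismatch")
  nSpeech <- sum(t == 1L)
  nNon <- sum(t == 0L)
  det <- if (nSpeech > 0) sum(p == 1L & t == 1L) / nSpeech else NA_real_
  fa <- if (nNon > 0) sum(p == 1L & t == 0L) / nNon else NA_real_
  c(detection = det, falseAlarm = fa)
}

#' Per-trial alignment errors and detection summaries
#'
#' Each trial is scored on the window from its cue onset to the next cue
#' onset (or the sequence end), so both missed speech and spurious
#' detections in the inter-trial interval are penalized. A trial counts as
#' majority-detected iff strictly more than 50\% of its reference speech
#' frames are predicted speech, and as not detected iff none of them are.
#' Trials with alignment error above the mean reference speech duration are
#' counted but not removed.
#'
#' @param pred binary \linkS4class{LabelSequence} for the session.
#' @param truth a \linkS4class{GroundTruth}.
#' @return list with \code{trialErrors} (data.frame: trial, errorMs,
#'   majorityDetected, notDetected), \code{nNotDetected},
#'   \code{majorityDetectionRate}, \code{nErrorAboveMeanDuration}.
#' @export
trialMetrics <- function(pred, truth) {
  stopifnot(is(pred, "LabelSequence"), is(truth, "GroundTruth"))
  tt <- trialTable(truth)
  if (nrow(tt) == 0) stop("empty trial table")
  tl <- truth@vadLabels@labels
  pl <- pred@labels
  shift <- pred@frameShift
  fps <- 1000 / shift  # frames per second
  T <- min(length(pl), length(tl))
  starts <- pmin(as.integer(round(tt$cueOnset * fps)), T)
  ends <- c(starts[-1], T)
  err <- numeric(nrow(tt))
  maj <- logical(nrow(tt))
  nd <- logical(nrow(tt))
  for (i in seq_len(nrow(tt))) {
    w <- if (ends[i] > starts[i]) (starts[i] + 1L):ends[i] else integer(0)
    err[i] <- shift * levenshtein_cpp(pl[w], tl[w])
    sp <- w[tl[w] == 1L]
    hit <- sum(pl[sp] == 1L)
    maj[i] <- length(sp) > 0 && hit > 0.5 * length(sp)
    nd[i] <- hit == 0L
  }
  meanDurMs <- mean(tt$speechOffset - tt$speechOnset) * 1000
  list(trialErrors = data.frame(trial = tt$trial, errorMs = err,
                                majorityDetected = maj, notDetected = nd),
       nNotDetected = sum(nd),
       majorityDetectionRate = mean(maj),
       nErrorAboveMeanDuration = sum(err > meanDurMs))
}

## ---- label sources ---------------------------------------------------------

# Per-day training labels: TICC-estimated, reference (ground truth VAD,
# standing in for the acoustic reference), or a shuffled control destroying
# the time correspondence while keeping the class ratio.
dayLabels <- function(framesZ, truth, source, hyper, seed) {
  ref <- truth@vadLabels
  T <- nFrames(framesZ)
  refLab <- ref@labels[seq_len(min(T, length(ref@labels)))]
  if (length(refLab) < T) refLab <- c(refLab, integer(T - length(refLab)))
  switch(source,
    reference = LabelSequence(refLab, frameShift = framesZ@frameShift),
    shuffled = {
      set.seed(seed)
      LabelSequence(sample(refLab), frameShift = framesZ@frameShift)
    },
    ticc = {
      hp <- hyper
      hp$seed <- seed
      fit <- fitTICC(framesZ, hp)
      relabel(fit$labels, inferClassMap(fit$labels))
    },
    stop("unknown label source: ", source))
}

#' Leave-one-day-out cross-validation
#'
#' For each fold one day is held out as the test set, the next remaining day
#' is withheld as validation, and the classifier is trained on the rest.
#' Every day is z-scored against its own baseline segment. Training and
#' validation labels come from \code{labelSource}: \code{"ticc"}
#' (unsupervised clustering labels), \code{"reference"} (the ground-truth
#' VAD, i.e. the acoustic-reference condition) or \code{"shuffled"} (a
#' permuted-label control). Evaluation is always against the ground truth
#' of the test day. A designated development day is excluded throughout.
#'
#' @param dataset list of day sessions, each a list with \code{dayId},
#'   \code{frames} (unnormalized \linkS4class{FrameSequence}),
#'   \code{baselineFrames} and \code{truth}
#'   (see \code{\link{makeSyntheticDataset}}).
#' @param cfg a \code{\link{trainingConfig}}.
#' @param labelSource \code{"ticc"}, \code{"reference"} or
#'   \code{"shuffled"}.
#' @param hyper \code{\link{ticcHyperparams}} for the TICC label source.
#' @param developmentDay optional dayId excluded from all folds.
#' @return An \linkS4class{EvalReport} with per-fold breakdowns.
#' @export
runLodoCV <- function(dataset, cfg = trainingConfig("rnn"),
                      labelSource = c("ticc", "reference", "shuffled"),
                      hyper = ticcHyperparams(),
                      developmentDay = NULL) {
  labelSource <- match.arg(labelSource)
  ids <- vapply(dataset, function(d) as.character(d$dayId), character(1))
  keep <- if (is.null(developmentDay)) seq_along(dataset) else
    which(ids != as.character(developmentDay))
  dataset <- dataset[keep]; ids <- ids[keep]
  nd <- length(dataset)
  if (nd < 3) stop("leave-one-day-out needs at least 3 days")
  # per-day normalization and training labels, computed once
  prep <- vector("list", nd)
  for (i in seq_len(nd)) {
    d <- dataset[[i]]
    stats <- fitBaselineStats(d$baselineFrames, source = ids[i])
    fz <- applyZscore(d$frames, stats)
    lab <- dayLabels(fz, d$truth, labelSource, hyper,
                     seed = cfg$seed + 997L * i)
    prep[[i]] <- list(frames = fz, labels = lab, truth = d$truth)
  }
  allTrials <- data.frame()
  perFold <- data.frame()
  tp <- fn <- fp <- tn <- 0
  nnd <- nerr <- 0L
  for (f in seq_len(nd)) {
    valIdx <- (f %% nd) + 1L  # next day, cyclically (never equals f)
    trainIdx <- setdiff(seq_len(nd), c(f, valIdx))
    cfgFold <- cfg
    cfgFold$seed <- cfg$seed + f
    model <- trainClassifier(prep[trainIdx], prep[valIdx], cfgFold)
    test <- prep[[f]]
    pred <- predictOffline(model, test$frames)
    tl <- test$truth@vadLabels@labels
    T <- min(length(tl), nFrames(pred))
    pl <- pred@labels[seq_len(T)]; tl <- tl[seq_len(T)]
    tp <- tp + sum(pl == 1 & tl == 1); fn <- fn + sum(pl == 0 & tl == 1)
    fp <- fp + sum(pl == 1 & tl == 0); tn <- tn + sum(pl == 0 & tl == 0)
    tm <- trialMetrics(pred, test$truth)
    te <- tm$trialErrors
    te$fold <- f; te$day <- ids[f]
    allTrials <- rbind(allTrials, te)
    nnd <- nnd + tm$nNotDetected
    nerr <- nerr + tm$nErrorAboveMeanDuration
    fr <- frameRates(LabelSequence(pl), LabelSequence(tl))
    perFold <- rbind(perFold, data.frame(
      fold = f, day = ids[f], nTrials = nrow(te),
      medianErrorMs = median(te$errorMs), detection = fr["detection"],
      falseAlarm = fr["falseAlarm"],
      majorityDetectionRate = tm$majorityDetectionRate,
      row.names = NULL))
  }
  new("EvalReport", trialErrors = allTrials,
      detectionProbability = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      falseAlarmProbability = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
      majorityDetectionRate = mean(allTrials$majorityDetected),
      nNotDetected = as.integer(nnd),
      nErrorAboveMeanDuration = as.integer(nerr), perFold = perFold)
}

#' Grid search over the TICC switching and sparsity penalties
#'
#' Fits TICC at every (beta, lambda) grid point on a calibration session
#' with reference labels, converts clusters to speech labels via the
#' minority rule, and returns the pair minimizing the median per-trial
#' alignment error, together with the full error table.
#'
#' @param calibration list with \code{frames} (z-scored
#'   \linkS4class{FrameSequence}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @param betaGrid,lamGrid numeric grids (non-empty).
#' @param hyper template \code{\link{ticcHyperparams}} supplying K, layers,
#'   dilation, seed.
#' @return list with \code{beta}, \code{lam} and \code{table} (data.frame:
#'   beta, lam, medianErrorMs).
#' @export
gridSearchHyperparams <- function(calibration, betaGrid = c(10, 50, 200),
                                  lamGrid = c(1e-4, 11e-4, 1e-2),
                                  hyper = ticcHyperparams()) {
  if (!length(betaGrid) || !length(lamGrid)) stop("grids must be non-empty")
  tab <- expand.grid(beta = betaGrid, lam = lamGrid,
                     KEEP.OUT.ATTRS = FALSE)
  tab$medianErrorMs <- NA_real_
  for (i in seq_len(nrow(tab))) {
    hp <- hyper
    hp$beta <- tab$beta[i]; hp$lam <- tab$lam[i]
    res <- tryCatch({
      fit <- fitTICC(calibration$frames, hp)
      lab <- relabel(fit$labels, inferClassMap(fit$labels))
      median(trialMetrics(lab, calibration$truth)$trialErrors$errorMs)
    }, error = function(e) NA_real_)
    tab$medianErrorMs[i] <- res
  }
  if (all(is.na(tab$medianErrorMs)))
    stop("all grid points degenerate")
  best <- which.min(tab$medianErrorMs)
  list(beta = tab$beta[best], lam = tab$lam[best], table = tab)
}

#' Channel contributions from the fitted cluster MRFs
#'
#' The precision matrices of the two clusters are read as adjacency
#' matrices of conditional dependencies between electrodes. For every
#' channel pair the absolute difference between the speech and non-speech
#' entries is computed on the within-time (lag-0) block; the same-electrode
#' term is the channel's contribution and the sum over all other
#' electrodes its total interdependency. Cross-lag blocks (multi-layer
#' models) are attached as attribute \code{"crossLag"}.
#'
#' @param model a fitted \linkS4class{TICCModel} with K = 2.
#' @param map optional class map from \code{\link{inferClassMap}} telling
#'   which cluster is speech (default: cluster 1).
#' @return data.frame with columns \code{channel}, \code{contribution},
#'   \code{interdependency}.
#' @export
channelContributions <- function(model, map = NULL) {
  stopifnot(is(model, "TICCModel"))
  if (length(model@clusters) != 2)
    stop("channel contributions require K = 2 clusters")
  speechIdx <- 2L
  if (!is.null(map))
    speechIdx <- as.integer(names(map)[map == "speech"]) + 1L
  sp <- model@clusters[[speechIdx]]
  ns <- model@clusters[[if (speechIdx == 1L) 2L else 1L]]
  C <- sp@nChannels
  w <- sp@nLayers
  d0 <- abs(sp@precision[1:C, 1:C] - ns@precision[1:C, 1:C])
  out <- data.frame(channel = seq_len(C), contribution = diag(d0),
                    interdependency = rowSums(d0) - diag(d0))
  if (w > 1) {
    cl <- lapply(seq_len(w - 1), function(s) {
      cols <- (s * C + 1):((s + 1) * C)
      abs(sp@precision[1:C, cols] - ns@precision[1:C, cols])
    })
    attr(out, "crossLag") <- cl
  }
  out
}

#' Energy-based reference voice activity detection
#'
#' Surrogate acoustic reference VAD: the audio is resampled to 16 kHz,
#' segmented into the same 50 ms / 10 ms grid as the neural features, and a
#' frame is speech when its smoothed (trailing 5-frame mean) log energy
#' exceeds an adaptive threshold — the 20th-percentile noise floor plus a
#' 10 dB margin, capped at an absolute level so sustained loud signal is
#' always detected.
#'
#' @param wave numeric audio waveform.
#' @param rate its sampling rate in Hz.
#' @param nFramesOut length of the neural frame grid to match (pad with
#'   non-speech / truncate).
#' @param frameShift,window frame grid in ms.
#' @param smoothFrames trailing moving-average length.
#' @param noisePercentile quantile estimating the noise floor.
#' @param marginDb margin above the noise floor.
#' @param capDb absolute threshold cap (dB re full scale).
#' @return binary \linkS4class{LabelSequence} on the neural frame grid.
#' @export
referenceVad <- function(wave, rate, nFramesOut = NULL, frameShift = 10,
                         window = 50, smoothFrames = 5L,
                         noisePercentile = 0.2, marginDb = 10,
                         capDb = -20) {
  fs <- 16000
  x <- if (rate != fs) as.numeric(signal::resample(wave, fs, rate)) else wave
  ws <- as.integer(window * fs / 1000)
  ss <- as.integer(frameShift * fs / 1000)
  T <- frameCount(length(x), ws, ss)
  logE <- numeric(T)
  for (i in seq_len(T)) {
    s0 <- (i - 1L) * ss
    logE[i] <- 10 * log10(mean(x[(s0 + 1L):(s0 + ws)]^2) + 1e-12)
  }
  sm <- logE
  k <- smoothFrames
  if (T > 1 && k > 1) {
    cs <- cumsum(logE)
    sm <- if (T > k) (cs - c(rep(0, k), cs[seq_len(T - k)])) /
      pmin(seq_len(T), k) else cs / seq_len(T)
  }
  lab <- if (T > 0) {
    thr <- min(quantile(logE, noisePercentile) + marginDb, capDb)
    as.integer(sm > thr)
  } else integer(0)
  if (!is.null(nFramesOut)) {
    if (length(lab) >= nFramesOut) lab <- lab[seq_len(nFramesOut)]
    else lab <- c(lab, integer(nFramesOut - length(lab)))
  }
  LabelSequence(lab, frameShift = frameShift)
}

#' Generate a multi-day synthetic dataset for cross-validation
#'
#' Runs the raw-session generator once per day (day-specific seeds and gain
#' drift), applies common average referencing, and extracts high-gamma
#' features for the whole day plus the baseline calibration segment.
#'
#' @param nDays number of days.
#' @param config template \code{\link{sessionConfig}}; each day uses
#'   \code{seed = config$seed + 1000 * day}.
#' @param selectedChannels optional channel subset after referencing.
#' @param includeAudio keep each day's audio track (memory-hungry).
#' @return list of day sessions (\code{dayId}, \code{frames},
#'   \code{baselineFrames}, \code{truth}, optionally \code{audio}).
#' @export
makeSyntheticDataset <- function(nDays, config = sessionConfig(),
                                 selectedChannels = NULL,
                                 includeAudio = FALSE) {
  out <- vector("list", nDays)
  for (d in seq_len(nDays)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * d
    ses <- generateRawSession(cfg)
    rec <- preprocessRaw(ses$recording, selectedChannels)
    fr <- extractHGPower(rec)
    nBase <- max(2L, as.integer(cfg$baselineDuration * 100) - 5L)
    base <- FrameSequence(fr@values[seq_len(min(nBase, nFrames(fr))), ,
                                    drop = FALSE],
                          frameShift = fr@frameShift, window = fr@window,
                          channelIds = fr@channelIds)
    out[[d]] <- c(list(dayId = d, frames = fr, baselineFrames = base,
                       truth = ses$truth),
                  if (includeAudio) list(audio = ses$audio))
  }
  out
}
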