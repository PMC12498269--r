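#' Synthetic session configuration
#'
#' Study conditions for the synthetic generator: a cued single-word reading
#' task (2 s word cue, 3 s inter-trial interval), 1 kHz multichannel
#' recordings on two electrode grids, band-limited (70-170 Hz) amplitude
#' bursts on a subset of "speech" channels during speaking, a 120 Hz
#' line-noise harmonic, per-day gain drift, and a speech-free calibration
#' segment at the start of each day standing in for the syllable task.
#'
#' @param nChannels total channel count (default 64).
#' @param nGrids number of electrode grids; channels are split evenly.
#' @param sampleRate sampling rate in Hz.
#' @param nTrials trials per session (default 100 = 50 words x 2).
#' @param cueDuration word-cue duration, s.
#' @param itiDuration inter-trial interval, s.
#' @param speechDurationMean,speechDurationSd,speechDurationMin truncated
#'   normal speech duration model, s (mean 1.2 matching the average spoken
#'   word duration).
#' @param speechOnsetDelay fixed reaction delay after cue onset, s.
#' @param speechOnsetJitter uniform onset jitter width, s.
#' @param speechChannelSet integer indices of channels carrying the speech
#'   modulation.
#' @param speechAmplitude burst amplitude relative to the total background
#'   standard deviation (0 disables the effect).
#' @param neuralLead lead of the neural (motor) modulation over the
#'   acoustic speech interval, s. Articulatory preparation precedes
#'   phonation, so the band-limited bursts start before — and end before —
#'   the acoustic ground-truth interval; this is the systematic
#'   neural/acoustic misalignment that bounds how well clustering-derived
#'   labels can match an acoustic reference.
#' @param sharedEnvelopeMix weight of the shared band-limited carrier in the
#'   bursts (spatial covariance structure the clustering exploits).
#' @param dayGainSd per-channel multiplicative day drift (log-scale sd).
#' @param lineNoiseHz,lineNoiseAmplitude line-noise harmonic parameters.
#' @param baselineDuration calibration segment length, s.
#' @param vocabularySize word pool size (50 training-like, 688
#'   generalization-like).
#' @param badChannels channel labels marked bad.
#' @param seed integer seed controlling every random draw.
#' @return A validated list of class \code{"sessionConfig"}.
#' @export
sessionConfig <- function(nChannels = 64L, nGrids = 2L, sampleRate = 1000,
                          nTrials = 100L, cueDuration = 2, itiDuration = 3,
                          speechDurationMean = 1.2, speechDurationSd = 0.25,
                          speechDurationMin = 0.3, speechOnsetDelay = 0.3,
                          speechOnsetJitter = 0.4,
                          speechChannelSet = seq_len(max(4L, nChannels %/% 4L)),
                          speechAmplitude = 0.5, neuralLead = 0.15,
                          sharedEnvelopeMix = 0.6,
                          dayGainSd = 0.05, lineNoiseHz = 120,
                          lineNoiseAmplitude = 0.5, baselineDuration = 30,
                          vocabularySize = 50L, badChannels = character(),
                          seed = 1L) {
  cfg <- list(nChannels = as.integer(nChannels), nGrids = as.integer(nGrids),
              sampleRate = sampleRate, nTrials = as.integer(nTrials),
              cueDuration = cueDuration, itiDuration = itiDuration,
              speechDurationMean = speechDurationMean,
              speechDurationSd = speechDurationSd,
              speechDurationMin = speechDurationMin,
              speechOnsetDelay = speechOnsetDelay,
              speechOnsetJitter = speechOnsetJitter,
              speechChannelSet = as.integer(speechChannelSet),
              speechAmplitude = speechAmplitude,
              neuralLead = neuralLead,
              sharedEnvelopeMix = sharedEnvelopeMix,
              dayGainSd = dayGainSd, lineNoiseHz = lineNoiseHz,
              lineNoiseAmplitude = lineNoiseAmplitude,
              baselineDuration = baselineDuration,
              vocabularySize = as.integer(vocabularySize),
              badChannels = as.character(badChannels),
              seed = as.integer(seed))
  durs <- c(cfg$cueDuration, cfg$itiDuration, cfg$speechDurationMean,
            cfg$baselineDuration)
  if (any(durs <= 0)) stop("all durations must be positive")
  if (cfg$cueDuration + cfg$itiDuration <= cfg$speechDurationMean)
    stop("cue + inter-trial interval must exceed the mean speech duration")
  if (length(cfg$speechChannelSet) == 0)
    stop("speechChannelSet must be non-empty")
  if (any(cfg$speechChannelSet < 1L | cfg$speechChannelSet > cfg$nChannels))
    stop("speechChannelSet out of channel range")
  class(cfg) <- "sessionConfig"
  cfg
}

#' Sample a block-Toeplitz sparse precision matrix
#'
#' Draws a random symmetric positive-definite precision matrix of size
#' (nLayers*nChannels)^2 whose w x w sub-blocks of size C depend only on the
#' block lag (block-Toeplitz), with approximately the requested off-diagonal
#' density. Used as a ground-truth Markov-random-field parameter for
#' cluster-recovery simulations.
#'
#' @param nChannels base dimension C (>= 2).
#' @param nLayers number of Toeplitz layers w (>= 1).
#' @param density fraction of non-zero off-diagonal entries per sub-block.
#' @param strength magnitude scale of the non-zero entries.
#' @param seed integer seed.
#' @param minEigen target minimum eigenvalue after diagonal loading.
#' @param maxTries bounded internal retries on numerically degenerate draws.
#' @return precision matrix with attribute \code{"blocks"} (the generating
#'   lag blocks).
#' @export
sampleBlockToeplitzPrecision <- function(nChannels, nLayers = 1L,
                                         density = 0.2, strength = 1,
                                         seed = 1L, minEigen = 0.1,
                                         maxTries = 10L) {
  stopifnot(nChannels >= 2, nLayers >= 1, density >= 0, density <= 1)
  C <- as.integer(nChannels); w <- as.integer(nLayers)
  set.seed(seed)
  for (try in seq_len(maxTries)) {
    blocks <- vector("list", w)
    # lag-0 block: symmetric, unit diagonal, sparse off-diagonal
    b0 <- diag(C)
    if (density > 0 && C > 1) {
      up <- which(upper.tri(b0))
      on <- up[runif(length(up)) < density]
      vals <- runif(length(on), strength / 2, strength) *
        sample(c(-1, 1), length(on), replace = TRUE)
      b0[on] <- vals
      b0 <- b0 + t(b0) - diag(diag(b0))
    }
    blocks[[1]] <- b0
    if (w > 1) for (s in 2:w) {
      bs <- matrix(0, C, C)
      if (density > 0) {
        on <- which(runif(C * C) < density)
        bs[on] <- runif(length(on), strength / 2, strength) *
          sample(c(-1, 1), length(on), replace = TRUE) * 0.5^(s - 1)
      }
      blocks[[s]] <- bs
    }
    theta <- assembleBlockToeplitz(blocks, C, w)
    ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < minEigen) theta <- theta + (minEigen - ev) * diag(w * C)
    ok <- tryCatch({ chol(theta); TRUE }, error = function(e) FALSE)
    if (ok) {
      attr(theta, "blocks") <- blocks
      return(theta)
    }
    set.seed(seed + try)
  }
  stop("failed to draw a positive-definite precision after ", maxTries,
       " attempts")
}

# Assemble full (wC x wC) matrix from lag blocks: sub-block (i,j) = B_{j-i},
# with B_{-s} = t(B_s).
assembleBlockToeplitz <- function(blocks, C, w) {
  theta <- matrix(0, w * C, w * C)
  for (i in seq_len(w)) for (j in seq_len(w)) {
    s <- j - i
    blk <- if (s >= 0) blocks[[s + 1]] else t(blocks[[-s + 1]])
    theta[((i - 1) * C + 1):(i * C), ((j - 1) * C + 1):(j * C)] <- blk
  }
  theta
}

#' Per-frame schedule for a cued-trial session
#'
#' Builds a binary per-frame plan (1 = speech) with \code{nTrials} speech
#' segments of \code{speechFrames} frames placed \code{onsetFrame} frames
#' into each \code{trialFrames}-frame trial.
#'
#' @param nTrials number of trials.
#' @param trialFrames frames per trial (500 = 5 s at 10 ms).
#' @param speechFrames speech frames per trial (120 = 1.2 s).
#' @param onsetFrame frame offset of speech within each trial.
#' @return integer 0/1 vector of length \code{nTrials * trialFrames}.
#' @export
trialSchedule <- function(nTrials, trialFrames = 500L, speechFrames = 120L,
                          onsetFrame = 50L) {
  stopifnot(onsetFrame + speechFrames <= trialFrames)
  lab <- integer(nTrials * trialFrames)
  for (i in seq_len(nTrials)) {
    s <- (i - 1L) * trialFrames + onsetFrame
    lab[(s + 1L):(s + speechFrames)] <- 1L
  }
  lab
}

#' Generate a feature-space session from two Markov random fields
#'
#' Draws each frame from the speech or non-speech Gaussian according to the
#' schedule, returning the frames and the schedule as exact ground truth.
#' This is the fixture for clustering recovery: the two classes differ in
#' mean and (block-Toeplitz) precision structure.
#'
#' @param schedule binary per-frame plan (see \code{\link{trialSchedule}}).
#' @param speechMrf,nonspeechMrf lists with elements \code{mean} and
#'   \code{precision} of equal dimension.
#' @param seed integer seed.
#' @return list with elements \code{frames} (\linkS4class{FrameSequence})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @export
generateFeatureSession <- function(schedule, speechMrf, nonspeechMrf,
                                   seed = 1L) {
  schedule <- as.integer(schedule)
  checkBinaryLabels(schedule, "schedule")
  d <- length(speechMrf$mean)
  if (length(nonspeechMrf$mean) != d ||
      !all(dim(speechMrf$precision) == c(d, d)) ||
      !all(dim(nonspeechMrf$precision) == c(d, d)))
    stop("speech and non-speech MRFs must share dimensions")
  T <- length(schedule)
  set.seed(seed)
  vals <- matrix(0, T, d)
  for (cls in 0:1) {
    idx <- which(schedule == cls)
    if (!length(idx)) next
    mrf <- if (cls == 1L) speechMrf else nonspeechMrf
    # draw N(mu, Theta^-1): solve R z with R the Cholesky of Theta
    R <- chol(mrf$precision)
    z <- matrix(rnorm(length(idx) * d), length(idx), d)
    vals[idx, ] <- t(backsolve(R, t(z))) +
      matrix(mrf$mean, length(idx), d, byrow = TRUE)
  }
  frames <- FrameSequence(vals, normalized = TRUE)
  labs <- LabelSequence(schedule)
  truth <- new("GroundTruth", vadLabels = labs,
               trialTable = trialTableFromLabels(schedule))
  list(frames = frames, truth = truth)
}

# Reconstruct a trial table from a binary frame sequence: one trial per
# speech run, cue assumed 0.5 s before onset (floored at the previous
# offset).
trialTableFromLabels <- function(labels, frameShift = 10) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sp <- which(r$values == 1L)
  dt <- frameShift / 1000
  tt <- data.frame(
    trial = seq_along(sp),
    wordId = seq_along(sp),
    cueOnset = pmax(0, (starts[sp] - 1L) * dt - 0.5),
    speechOnset = (starts[sp] - 1L) * dt,
    speechOffset = ends[sp] * dt
  )
  if (length(sp) > 1)
    tt$cueOnset <- pmax(tt$cueOnset, c(0, ends[sp[-length(sp)]] * dt))
  tt
}

#' Generate a raw synthetic recording session
#'
#' Produces a 1 kHz multichannel recording with: 1/f (pink) background noise
#' per channel plus a shared per-grid common-mode component (so common
#' average referencing is exercised), a line-noise harmonic, band-limited
#' (70-170 Hz) amplitude bursts on the speech channel subset during speech
#' intervals driven by a shared latent envelope with per-channel loadings,
#' per-channel day gain drift, and a speech-free calibration segment at the
#' start. A 48 kHz noise-burst audio track aligned to the speech intervals
#' is returned for the reference acoustic VAD.
#'
#' Speech onsets are cue onset + fixed delay + uniform jitter; durations are
#' truncated normal. Intervals are quantized to the 10 ms frame grid so the
#' frame labels reconstruct the trial table exactly.
#'
#' @param config a \code{\link{sessionConfig}}.
#' @return list with \code{recording} (\linkS4class{RawRecording}),
#'   \code{truth} (\linkS4class{GroundTruth}), \code{audio} (list with
#'   \code{wave}, \code{rate}), and \code{config}. The calibration segment
#'   is marked on the trial table as attribute \code{"baseline"} (interval
#'   in seconds).
#' @export
generateRawSession <- function(config = sessionConfig()) {
  stopifnot(inherits(config, "sessionConfig"))
  cfg <- config
  fs <- cfg$sampleRate
  set.seed(cfg$seed)
  trialLen <- cfg$cueDuration + cfg$itiDuration
  totalDur <- cfg$baselineDuration + cfg$nTrials * trialLen
  n <- as.integer(round(totalDur * fs))
  C <- cfg$nChannels

  # trial timing, quantized to the 10 ms frame grid
  cueOnsets <- cfg$baselineDuration + (seq_len(cfg$nTrials) - 1) * trialLen
  onsets <- cueOnsets + cfg$speechOnsetDelay +
    runif(cfg$nTrials, 0, cfg$speechOnsetJitter)
  durs <- rtruncnorm(cfg$nTrials, cfg$speechDurationMean,
                     cfg$speechDurationSd, cfg$speechDurationMin)
  offsets <- pmin(onsets + durs, cueOnsets + trialLen - 0.05)
  onsets <- round(onsets, 2)
  offsets <- round(offsets, 2)
  wordIds <- sample(rep(seq_len(cfg$vocabularySize),
                        length.out = cfg$nTrials))

  # background: per-channel pink noise + per-grid common mode
  x <- pinkNoise(n, C)
  gridOf <- rep(seq_len(cfg$nGrids), each = ceiling(C / cfg$nGrids),
                length.out = C)
  cm <- pinkNoise(n, cfg$nGrids)
  x <- x + cm[, gridOf]

  # line-noise harmonic, random phase per channel
  tt <- seq_len(n) / fs
  phases <- runif(C, 0, 2 * pi)
  for (c in seq_len(C))
    x[, c] <- x[, c] + cfg$lineNoiseAmplitude *
      sin(2 * pi * cfg$lineNoiseHz * tt + phases[c])

  # speech bursts: shared + private band-limited carriers, smooth envelope
  if (cfg$speechAmplitude > 0) {
    env <- numeric(n)
    ramp <- 0.1  # s, raised-cosine edges
    for (i in seq_len(cfg$nTrials)) {
      # neural modulation leads the acoustic interval by neuralLead
      i0 <- as.integer(max(0, onsets[i] - cfg$neuralLead) * fs)
      i1 <- as.integer(max(0, offsets[i] - cfg$neuralLead) * fs)
      if (i1 <= i0) next
      seg <- numeric(i1 - i0)
      m <- length(seg)
      nr <- min(as.integer(ramp * fs), m %/% 2)
      seg[] <- 1
      if (nr > 0) {
        up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
        seg[seq_len(nr)] <- up
        seg[m - nr + seq_len(nr)] <- rev(up)
      }
      env[(i0 + 1):i1] <- seg
    }
    bpf <- designHGFilters(fs)$bandpass
    shared <- sosApply(matrix(rnorm(n), n, 1), bpf)$y[, 1]
    shared <- shared / sd(shared)
    # syllabic-rate (~4 Hz) amplitude modulation, partly shared across the
    # speech channels and partly channel-private: articulator-related
    # channels wax and wane together within a word without collapsing to a
    # single common factor, giving speech frames a full-rank block of
    # conditional dependencies in window-power space (the structure the
    # cluster MRFs pick up)
    lpf <- tf2sos(signal::butter(2, 5 / (fs / 2), type = "low")$b,
                  signal::butter(2, 5 / (fs / 2), type = "low")$a)
    mShared <- sosApply(matrix(rnorm(n), n, 1), lpf)$y[, 1]
    mShared <- mShared / sd(mShared)
    alpha <- cfg$sharedEnvelopeMix
    loadings <- exp(rnorm(length(cfg$speechChannelSet), 0, 0.15))
    # background per-channel sd is ~sqrt(2) (pink + common mode, each sd 1)
    amp <- cfg$speechAmplitude * sqrt(2)
    for (j in seq_along(cfg$speechChannelSet)) {
      ch <- cfg$speechChannelSet[j]
      priv <- sosApply(matrix(rnorm(n), n, 1), bpf)$y[, 1]
      priv <- priv / sd(priv)
      carrier <- alpha * shared + sqrt(1 - alpha^2) * priv
      mPriv <- sosApply(matrix(rnorm(n), n, 1), lpf)$y[, 1]
      am <- exp(0.3 * (alpha * mShared +
                         sqrt(1 - alpha^2) * mPriv / sd(mPriv)))
      x[, ch] <- x[, ch] + amp * loadings[j] * env * am * carrier
    }
  }

  # day-specific multiplicative gain drift
  gains <- exp(rnorm(C, 0, cfg$dayGainSd))
  x <- sweep(x, 2, gains, "*")

  channelIds <- paste0("ch", seq_len(C))
  rec <- RawRecording(x, sampleRate = fs, channelIds = channelIds,
                      gridOfChannel = gridOf, badChannels = cfg$badChannels)

  # frame-level ground truth (frame i covers [i*shift, i*shift + window))
  T <- frameCount(n, as.integer(0.05 * fs), as.integer(0.01 * fs))
  lab <- integer(T)
  for (i in seq_len(cfg$nTrials)) {
    f0 <- as.integer(round(onsets[i] * 100))
    f1 <- as.integer(round(offsets[i] * 100))
    f1 <- min(f1, T)
    if (f1 > f0) lab[(f0 + 1):f1] <- 1L
  }
  trialTab <- data.frame(trial = seq_len(cfg$nTrials), wordId = wordIds,
                         cueOnset = cueOnsets, speechOnset = onsets,
                         speechOffset = offsets)
  attr(trialTab, "baseline") <- c(0, cfg$baselineDuration)
  truth <- new("GroundTruth", vadLabels = LabelSequence(lab),
               trialTable = trialTab)

  # aligned audio surrogate: white-noise bursts at 48 kHz
  arate <- 48000
  an <- as.integer(round(totalDur * arate))
  audio <- rnorm(an, 0, 1e-4)
  for (i in seq_len(cfg$nTrials)) {
    a0 <- as.integer(onsets[i] * arate); a1 <- as.integer(offsets[i] * arate)
    if (a1 > a0) audio[(a0 + 1):a1] <- audio[(a0 + 1):a1] +
        rnorm(a1 - a0, 0, 0.3)
  }

  list(recording = rec, truth = truth,
       audio = list(wave = audio, rate = arate), config = cfg)
}
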