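# Shared fixtures, built once per test run (lazily, memoized).

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# Feature-space session from two well-separated disjoint-support MRFs.
fxFeatureSession <- function() fixture("featureSession", function() {
  pp <- disjointPrecisionPair(8, seed = 42)
  sched <- trialSchedule(20, trialFrames = 250, speechFrames = 120,
                         onsetFrame = 40)
  ses <- generateFeatureSession(
    sched, list(mean = rep(0, 8), precision = pp$speech),
    list(mean = rep(0, 8), precision = pp$nonspeech), seed = 7)
  ses$schedule <- sched
  ses$precisions <- pp
  ses
})

# Small raw session with preprocessing, features and z-scoring done.
fxRawSession <- function() fixture("rawSession", function() {
  cfg <- sessionConfig(nChannels = 12, nGrids = 2, nTrials = 5,
                       baselineDuration = 8, speechChannelSet = c(2, 5, 8),
                       seed = 31)
  ses <- generateRawSession(cfg)
  rec <- preprocessRaw(ses$recording)
  fr <- extractHGPower(rec)
  nb <- as.integer(cfg$baselineDuration * 100) - 5L
  base <- FrameSequence(frameValues(fr)[seq_len(nb), , drop = FALSE],
                        channelIds = channelIds(fr))
  stats <- fitBaselineStats(base)
  list(cfg = cfg, session = ses, rec = rec, frames = fr, base = base,
       stats = stats, fz = applyZscore(fr, stats))
})

# Quickly trained classifiers on a small separable session (all archs).
fxModels <- function() fixture("models", function() {
  set.seed(99)
  C <- 8; lab <- trialSchedule(6, 250, 120, 40)
  X <- matrix(rnorm(length(lab) * C), ncol = C) + outer(lab, rep(1.5, C))
  fr <- FrameSequence(X, normalized = TRUE)
  ls <- LabelSequence(lab)
  ses <- list(frames = fr, labels = ls)
  models <- lapply(c(logreg = "logreg", cnn = "cnn", rnn = "rnn"),
                   function(a)
    trainClassifier(list(ses), list(ses),
                    trainingConfig(a, epochs = 2L, seed = 4)))
  list(models = models, frames = fr, labels = lab)
})
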