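test_that("alignment error is 10 ms per edit operation", {
  a <- LabelSequence(c(0L, 0L, 1L, 1L, 1L, 0L))
  b <- LabelSequence(c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(alignmentError(a, b), 20)
  expect_equal(alignmentError(a, a), 0)
  # all-zero prediction vs S speech frames: exactly 10 * S
  t <- LabelSequence(c(rep(0L, 30), rep(1L, 12), rep(0L, 30)))
  p <- LabelSequence(rep(0L, 72))
  expect_equal(alignmentError(p, t), 120)
  expect_error(alignmentError(LabelSequence(c(0L, 2L)), a), "binary")
  expect_error(alignmentError(a, LabelSequence(0L, frameShift = 20)),
               "frame shift")
})

test_that("alignment error behaves as a metric with the known bounds", {
  set.seed(31)
  for (i in 1:25) {
    x <- randomBinaryLabels(sample(5:60, 1))
    y <- randomBinaryLabels(sample(5:60, 1))
    z <- randomBinaryLabels(sample(5:60, 1))
    dxy <- alignmentError(x, y)
    expect_equal(dxy, alignmentError(y, x))
    expect_lte(dxy, alignmentError(x, z) + alignmentError(z, y))
    expect_lte(dxy, 10 * max(nFrames(x), nFrames(y)))
    expect_equal(alignmentError(x, x), 0)
  }
  # equal lengths: bounded by 10 * Hamming distance
  for (i in 1:10) {
    x <- randomBinaryLabels(40); y <- randomBinaryLabels(40)
    expect_lte(alignmentError(x, y),
               10 * sum(labels01(x) != labels01(y)))
  }
})

test_that("detection and false-alarm probabilities count frames correctly", {
  t <- LabelSequence(c(0L, 0L, 1L, 1L))
  expect_equal(unname(frameRates(t, t)), c(1, 0))
  expect_equal(unname(frameRates(LabelSequence(rep(1L, 4)), t)), c(1, 1))
  # pred 0101 vs target 0011: detection 1/2, false alarm 1/2
  expect_equal(unname(frameRates(LabelSequence(c(0L, 1L, 0L, 1L)), t)),
               c(0.5, 0.5))
  # undefined denominators are NA, not 0
  allSpeech <- LabelSequence(rep(1L, 4))
  expect_true(is.na(frameRates(t, allSpeech)["falseAlarm"]))
  expect_true(is.na(frameRates(t, LabelSequence(rep(0L, 4)))["detection"]))
  expect_error(frameRates(t, LabelSequence(0L)), "length")
  # invariant to concatenation order of trials
  set.seed(32)
  p1 <- randomBinaryLabels(50); t1 <- randomBinaryLabels(50)
  p2 <- randomBinaryLabels(70); t2 <- randomBinaryLabels(70)
  ab <- frameRates(LabelSequence(c(labels01(p1), labels01(p2))),
                   LabelSequence(c(labels01(t1), labels01(t2))))
  ba <- frameRates(LabelSequence(c(labels01(p2), labels01(p1))),
                   LabelSequence(c(labels01(t2), labels01(t1))))
  expect_equal(ab, ba)
})

test_that("trial metrics apply the majority and non-detection rules", {
  # 3 trials, 10 speech frames each, windows of 100 frames
  lab <- integer(300)
  lab[41:50] <- 1L; lab[141:150] <- 1L; lab[241:250] <- 1L
  tt <- data.frame(trial = 1:3, wordId = 1:3, cueOnset = c(0, 1, 2),
                   speechOnset = c(0.40, 1.40, 2.40),
                   speechOffset = c(0.50, 1.50, 2.50))
  truth <- new("GroundTruth", vadLabels = LabelSequence(lab),
               trialTable = tt)
  # hit 60%, 40%, 100% of each trial's speech frames
  pred <- integer(300)
  pred[41:46] <- 1L; pred[141:144] <- 1L; pred[241:250] <- 1L
  tm <- trialMetrics(LabelSequence(pred), truth)
  expect_equal(tm$majorityDetectionRate, 2 / 3)
  expect_equal(tm$nNotDetected, 0L)
  # perfect prediction
  tmP <- trialMetrics(LabelSequence(lab), truth)
  expect_equal(tmP$majorityDetectionRate, 1)
  expect_equal(tmP$trialErrors$errorMs, rep(0, 3))
  expect_equal(tmP$nNotDetected, 0L)
  # all-non-speech prediction: nothing detected
  tm0 <- trialMetrics(LabelSequence(integer(300)), truth)
  expect_equal(tm0$majorityDetectionRate, 0)
  expect_equal(tm0$nNotDetected, 3L)
  expect_error(trialMetrics(LabelSequence(pred),
                            new("GroundTruth",
                                vadLabels = LabelSequence(lab),
                                trialTable = tt[0, ])), "empty")
})

test_that("the energy-based reference VAD tracks the synthetic audio", {
  # digital silence: all non-speech
  sil <- referenceVad(rep(0, 48000), 48000)
  expect_true(all(labels01(sil) == 0L))
  # constant full-scale noise: all speech after warm-up
  set.seed(33)
  loud <- referenceVad(rnorm(48000, 0, 0.5), 48000)
  expect_true(all(labels01(loud)[-(1:10)] == 1L))
  # synthetic session audio recovers the ground-truth intervals
  fx <- fxRawSession()
  rv <- referenceVad(fx$session$audio$wave, fx$session$audio$rate,
                     nFramesOut = nFrames(vadLabels(fx$session$truth)))
  fr <- frameRates(rv, vadLabels(fx$session$truth))
  expect_gte(fr["detection"], 0.95)
  expect_lte(fr["falseAlarm"], 0.05)
})

test_that("channel contributions localize the differing dependencies", {
  d <- 6
  base <- crossprod(matrix(rnorm(d * d), d)) / d + diag(d)
  clA <- neurovad:::makeMRFCluster(rep(0, d), base, 10L, 1L, d)
  clB <- neurovad:::makeMRFCluster(rep(0, d), base, 10L, 1L, d)
  mk <- function(a, b) new("TICCModel", clusters = list(a, b),
                           hyper = unclass(ticcHyperparams()),
                           objectiveTrace = numeric(), converged = TRUE,
                           nIter = 1L)
  # identical precisions: all-zero map
  cm0 <- channelContributions(mk(clA, clB))
  expect_equal(cm0$contribution, rep(0, d))
  expect_equal(cm0$interdependency, rep(0, d))
  # difference restricted to channels S = {2, 5}
  pert <- base
  pert[2, 5] <- pert[2, 5] + 0.8; pert[5, 2] <- pert[2, 5]
  pert[2, 2] <- pert[2, 2] + 0.5
  clC <- neurovad:::makeMRFCluster(rep(0, d), pert, 10L, 1L, d)
  cm <- channelContributions(mk(clA, clC))
  expect_true(all(order(cm$interdependency, decreasing = TRUE)[1:2] %in%
                    c(2, 5)))
  expect_equal(which.max(cm$contribution), 2L)
  expect_error(channelContributions(
    new("TICCModel", clusters = list(clA),
        hyper = unclass(ticcHyperparams()), objectiveTrace = numeric(),
        converged = TRUE, nIter = 1L)), "K = 2")
})

test_that("grid search scores every point and returns the best", {
  ses <- fxFeatureSession()
  cal <- list(frames = ses$frames, truth = ses$truth)
  # single-point grid returns that point
  g1 <- gridSearchHyperparams(cal, betaGrid = 50, lamGrid = 11e-4,
                              hyper = ticcHyperparams(seed = 1))
  expect_equal(g1$beta, 50)
  expect_equal(g1$lam, 11e-4)
  expect_equal(nrow(g1$table), 1L)
  expect_error(gridSearchHyperparams(cal, betaGrid = numeric()), "non-empty")
})

test_that("grid search prefers the temporally regularized setting on noisy data", {
  # low-SNR session: without the switching penalty the labels fragment,
  # with beta = 50 the segments are recovered
  cfg <- sessionConfig(nChannels = 8, nGrids = 1, nTrials = 12,
                       baselineDuration = 8, speechChannelSet = 1:3,
                       speechAmplitude = 0.35, seed = 66)
  ses <- generateRawSession(cfg)
  fr <- extractHGPower(preprocessRaw(ses$recording))
  base <- FrameSequence(frameValues(fr)[1:795, , drop = FALSE],
                        channelIds = channelIds(fr))
  fz <- applyZscore(fr, fitBaselineStats(base))
  gs <- gridSearchHyperparams(list(frames = fz, truth = ses$truth),
                              betaGrid = c(0, 50), lamGrid = 11e-4,
                              hyper = ticcHyperparams(seed = 2))
  expect_equal(nrow(gs$table), 2L)
  expect_equal(gs$beta, gs$table$beta[which.min(gs$table$medianErrorMs)])
  expect_equal(gs$beta, 50)
  expect_lt(gs$table$medianErrorMs[gs$table$beta == 50],
            gs$table$medianErrorMs[gs$table$beta == 0])
})

test_that("alignment error shrinks as the injected effect grows", {
  meds <- vapply(c(0.25, 0.5, 1.0), function(a) {
    cfg <- sessionConfig(nChannels = 8, nGrids = 1, nTrials = 6,
                         baselineDuration = 8, speechChannelSet = 1:3,
                         speechAmplitude = a, neuralLead = 0, seed = 55)
    ses <- generateRawSession(cfg)
    fr <- extractHGPower(preprocessRaw(ses$recording))
    nb <- as.integer(cfg$baselineDuration * 100) - 5L
    base <- FrameSequence(frameValues(fr)[seq_len(nb), , drop = FALSE],
                          channelIds = channelIds(fr))
    fz <- applyZscore(fr, fitBaselineStats(base))
    fit <- fitTICC(fz, ticcHyperparams(seed = 5))
    bin <- relabel(fit$labels, inferClassMap(fit$labels))
    median(trialMetrics(bin, ses$truth)$trialErrors$errorMs)
  }, numeric(1))
  expect_true(all(diff(meds) <= 0))
})

test_that("the LODO harness excludes the development day and validates size", {
  cfg <- sessionConfig(nChannels = 8, nGrids = 1, nTrials = 3,
                       baselineDuration = 6, speechChannelSet = 1:3,
                       seed = 77)
  ds <- makeSyntheticDataset(4, cfg)
  rep <- runLodoCV(ds, trainingConfig("logreg", seed = 1),
                   labelSource = "reference", developmentDay = 2)
  expect_equal(nrow(rep@perFold), 3L)
  expect_false("2" %in% rep@perFold$day)
  expect_error(runLodoCV(ds[1:2], trainingConfig("logreg"),
                         labelSource = "reference"), "3 days")
  expect_error(runLodoCV(ds, trainingConfig("logreg"),
                         labelSource = "reference", developmentDay = 1,
                         hyper = ticcHyperparams()), NA)
})
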