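test_that("block-Toeplitz precision sampler honors structure and density", {
  # density 0: diagonal-only (scaled identity)
  th0 <- sampleBlockToeplitzPrecision(6, 1, density = 0, seed = 3)
  expect_equal(th0, diag(diag(th0)), ignore_attr = TRUE)

  # PD by construction
  th <- sampleBlockToeplitzPrecision(4, 1, density = 0.5, seed = 5)
  expect_gt(min(eigen(th, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(th, t(th), ignore_attr = TRUE)

  # w = 3: sub-block at each lag identical wherever it appears
  C <- 4; w <- 3
  th3 <- sampleBlockToeplitzPrecision(C, w, density = 0.3, seed = 8)
  blockAt <- function(i, j)
    th3[((i - 1) * C + 1):(i * C), ((j - 1) * C + 1):(j * C)]
  for (i in seq_len(w - 1)) for (j in seq_len(w - 1))
    expect_equal(blockAt(i, j), blockAt(i + 1, j + 1))
})

test_that("feature sessions sample from the scheduled cluster", {
  ses <- fxFeatureSession()
  # labels returned exactly as scheduled
  expect_identical(labels01(vadLabels(ses$truth)), ses$schedule)

  # all-non-speech schedule
  pp <- ses$precisions
  s0 <- generateFeatureSession(integer(100),
                               list(mean = rep(0, 8), precision = pp$speech),
                               list(mean = rep(0, 8),
                                    precision = pp$nonspeech), seed = 1)
  expect_true(all(labels01(vadLabels(s0$truth)) == 0L))

  # dimension mismatch
  expect_error(generateFeatureSession(
    c(0L, 1L), list(mean = rep(0, 3), precision = diag(3)),
    list(mean = rep(0, 4), precision = diag(4))), "dimensions")

  # empirical speech covariance closer (Frobenius) to the speech MRF's
  X <- frameValues(ses$frames)
  Ss <- cov(X[ses$schedule == 1, ])
  dS <- norm(Ss - solve(pp$speech), "F")
  dN <- norm(Ss - solve(pp$nonspeech), "F")
  expect_lt(dS, dN)
})

test_that("near-identical clusters carry no recoverable label information", {
  pp <- disjointPrecisionPair(6, seed = 11)
  sched <- trialSchedule(8, trialFrames = 100, speechFrames = 50,
                         onsetFrame = 20)
  ses <- generateFeatureSession(
    sched, list(mean = rep(0.01, 6), precision = pp$speech),
    list(mean = rep(0, 6), precision = pp$speech), seed = 2)
  acc <- tryCatch({
    fit <- fitTICC(ses$frames, ticcHyperparams(seed = 3, maxIter = 20L))
    lab <- labels01(fit$labels)
    max(mean(lab == sched), mean((1L - lab) == sched))
  }, error = function(e) NA_real_)  # degenerate collapse is acceptable
  if (!is.na(acc)) expect_lt(acc, 0.75)
  else succeed("clustering collapsed on uninformative data")
})

test_that("raw sessions are deterministic with the session arithmetic", {
  fx <- fxRawSession()
  cfg <- fx$cfg
  # bit-identical regeneration
  again <- generateRawSession(cfg)
  expect_identical(rawSamples(fx$session$recording),
                   rawSamples(again$recording))
  expect_identical(fx$session$audio$wave, again$audio$wave)
  # schedule arithmetic: baseline + nTrials * (cue + iti)
  dur <- nrow(rawSamples(fx$session$recording)) / cfg$sampleRate
  expect_gte(dur, cfg$baselineDuration + cfg$nTrials * 5)
  # ground-truth labels reconstruct the trial table by segment extraction
  segs <- labelsToSegments(vadLabels(fx$session$truth))
  sp <- segs[segs$label == 1L, ]
  tt <- trialTable(fx$session$truth)
  expect_equal(nrow(sp), nrow(tt))
  expect_equal(sp$start / 100, tt$speechOnset, tolerance = 1e-9)
  expect_equal(sp$end / 100, tt$speechOffset, tolerance = 1e-9)
  # baseline marked on the trial table
  expect_equal(attr(tt, "baseline"), c(0, cfg$baselineDuration))
})

test_that("zero speech amplitude leaves high-gamma power uninformative", {
  cfg <- sessionConfig(nChannels = 8, nGrids = 1, nTrials = 5,
                       baselineDuration = 6, speechChannelSet = 1:3,
                       speechAmplitude = 0, seed = 17)
  ses <- generateRawSession(cfg)
  fr <- extractHGPower(preprocessRaw(ses$recording))
  tl <- labels01(vadLabels(ses$truth))[seq_len(nFrames(fr))]
  v <- frameValues(fr)
  d <- vapply(seq_len(ncol(v)), function(c)
    abs(mean(v[tl == 1, c]) - mean(v[tl == 0, c])) / sd(v[tl == 0, c]),
    numeric(1))
  expect_lt(max(d), 0.35)
})

test_that("injected effect is band-limited (low frequencies untouched)", {
  fx <- fxRawSession()
  x <- rawSamples(fx$session$recording)
  tl <- labels01(vadLabels(fx$session$truth))
  ch <- fx$cfg$speechChannelSet[1]
  # low-pass below 40 Hz, then frame power on the same grid
  lp <- signal::butter(4, 40 / 500, type = "low")
  xl <- as.numeric(signal::filter(lp, x[, ch]))
  T <- min(length(tl), (length(xl) - 50) %/% 10 + 1)
  pw <- vapply(seq_len(T), function(i)
    mean(xl[((i - 1) * 10 + 1):((i - 1) * 10 + 50)]^2), numeric(1))
  eff <- abs(mean(pw[tl[1:T] == 1]) - mean(pw[tl[1:T] == 0])) /
    sd(pw[tl[1:T] == 0])
  expect_lt(eff, 0.35)
})

test_that("session configuration is validated", {
  expect_error(sessionConfig(speechChannelSet = integer()), "non-empty")
  expect_error(sessionConfig(speechChannelSet = 99, nChannels = 8), "range")
  expect_error(sessionConfig(cueDuration = 0.5, itiDuration = 0.5),
               "exceed")
  expect_error(sessionConfig(baselineDuration = -1), "positive")
})
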