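test_that("common average referencing removes per-grid common mode", {
  # identical signals on one grid -> all-zero after CAR
  x <- matrix(rep(sin(seq_len(500) / 10), 4), ncol = 4)
  rec <- RawRecording(x, gridOfChannel = rep(1L, 4))
  out <- rawSamples(preprocessRaw(rec))
  expect_equal(max(abs(out)), 0)

  # single-channel grid is zeroed (mean of itself)
  rec1 <- RawRecording(cbind(rnorm(100), rnorm(100)),
                       gridOfChannel = c(1L, 2L))
  out1 <- rawSamples(preprocessRaw(rec1))
  expect_equal(max(abs(out1[, 2])), 0)
  expect_equal(max(abs(out1[, 1])), 0)

  # distinct DC offsets removed independently per grid
  set.seed(2)
  x2 <- matrix(rnorm(200 * 6), 200, 6)
  x2[, 1:3] <- x2[, 1:3] + 100
  x2[, 4:6] <- x2[, 4:6] - 55
  rec2 <- RawRecording(x2, gridOfChannel = rep(1:2, each = 3L))
  out2 <- rawSamples(preprocessRaw(rec2))
  expect_lt(max(abs(rowMeans(out2[, 1:3]))), 1e-10)
  expect_lt(max(abs(rowMeans(out2[, 4:6]))), 1e-10)
  expect_lt(max(abs(colMeans(out2))), 1)
})

test_that("CAR commutes with channel permutation within a grid and drops bad channels", {
  set.seed(3)
  x <- matrix(rnorm(300 * 5), 300, 5)
  rec <- RawRecording(x, channelIds = paste0("c", 1:5),
                      gridOfChannel = rep(1L, 5), badChannels = "c3")
  a <- preprocessRaw(rec, c("c1", "c5"))
  perm <- c(2, 1, 3, 5, 4)
  recP <- RawRecording(x[, perm], channelIds = paste0("c", 1:5)[perm],
                       gridOfChannel = rep(1L, 5), badChannels = "c3")
  b <- preprocessRaw(recP, c("c1", "c5"))
  expect_equal(rawSamples(a), rawSamples(b))
  expect_error(preprocessRaw(rec, c("c3")), "bad")
  expect_error(preprocessRaw(rec, c("nope")), "unknown")
})

test_that("high-gamma framing follows the 50 ms / 10 ms convention", {
  rec <- RawRecording(matrix(rnorm(1050 * 2), 1050, 2))
  fr <- extractHGPower(rec)
  expect_equal(nFrames(fr), 101L)  # floor((1050-50)/10)+1
  # shorter than one window: empty, not an error
  fr0 <- extractHGPower(RawRecording(matrix(rnorm(49 * 2), 49, 2)))
  expect_equal(nFrames(fr0), 0L)
  # silence floors at log(eps)
  frz <- extractHGPower(RawRecording(matrix(0, 400, 2)))
  expect_equal(unique(as.vector(frameValues(frz))), log(1e-10))
})

test_that("the notch attenuates 120 Hz by the cascade's designed response", {
  fs <- 1000
  filt <- designHGFilters(fs)
  tt <- seq_len(6000) / fs
  mag <- function(f) abs(neurovad:::sosFreqResponse(filt$bandpass, f, fs) *
                           neurovad:::sosFreqResponse(filt$bandstop, f, fs))
  measure <- function(f) {
    rec <- RawRecording(matrix(sin(2 * pi * f * tt), ncol = 1))
    v <- frameValues(extractHGPower(rec))
    mean(v[400:590, 1])  # steady state
  }
  # derived oracle: expected log frame power = log(amp^2 |H|^2 / 2 + eps)
  for (f in c(100, 120)) {
    expected <- log(mag(f)^2 / 2 + 1e-10)
    expect_equal(measure(f), expected, tolerance = 0.05)
  }
  # 120 Hz sits below 100 Hz by at least the floor-limited attenuation
  floorLimited <- log(mag(100)^2 / 2 + 1e-10) - log(mag(120)^2 / 2 + 1e-10)
  expect_gt(measure(100) - measure(120), 0.95 * floorLimited)
  expect_gt(floorLimited, 20)  # > 20 nats: far below the pass band
})

test_that("z-scoring is exact against its own baseline and floors degenerate sd", {
  set.seed(4)
  fr <- FrameSequence(matrix(rnorm(200 * 3, mean = 5), 200, 3))
  st <- fitBaselineStats(fr)
  z <- applyZscore(fr, st)
  expect_equal(colMeans(frameValues(z)), rep(0, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # population convention: variance exactly 1
  expect_equal(apply(frameValues(z), 2, function(x) mean(x^2)), rep(1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(z@normalized)

  const <- FrameSequence(cbind(rnorm(50), rep(3, 50)))
  expect_warning(stc <- fitBaselineStats(const), "floored")
  zc <- applyZscore(const, stc)
  expect_equal(unique(frameValues(zc)[, 2]), 0)
  expect_error(fitBaselineStats(FrameSequence(matrix(1, 1, 2))), "2 frames")
})

test_that("cross-day gain drift shifts features by the log-domain offset", {
  fx <- fxRawSession()
  g <- 1.35
  x <- rawSamples(fx$rec)
  recG <- RawRecording(x * g, channelIds = channelIds(fx$rec),
                       gridOfChannel = fx$rec@gridOfChannel)
  frG <- extractHGPower(recG)
  # log power shifts by 2*log(g) per feature (window power scales with g^2)
  delta <- frameValues(frG) - frameValues(fx$frames)
  expect_equal(mean(delta), 2 * log(g), tolerance = 1e-6)
  expect_lt(sd(delta), 1e-6)
  # applying day-A stats to gained day: z means shift by 2 log g / sd
  zG <- applyZscore(frG, fx$stats)
  z0 <- applyZscore(fx$frames, fx$stats)
  shift <- colMeans(frameValues(zG)) - colMeans(frameValues(z0))
  expect_equal(shift, 2 * log(g) / fx$stats@sd, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("context stacking concatenates zero-padded past frames", {
  set.seed(5)
  fr <- FrameSequence(matrix(rnorm(100 * 4), 100, 4))
  # identity under lags = (0)
  expect_equal(frameValues(stackContext(fr, 0L)), frameValues(fr),
               ignore_attr = TRUE)
  # default 7 lags: 100 x 28; row 0 = (x0, 0, ..., 0)
  st <- stackContext(fr)
  expect_equal(dim(frameValues(st)), c(100L, 28L))
  expect_equal(frameValues(st)[1, 1:4], frameValues(fr)[1, ],
               ignore_attr = TRUE)
  expect_equal(frameValues(st)[1, 5:28], rep(0, 24), ignore_attr = TRUE)
  # row t concatenates x[t - lag]
  expect_equal(frameValues(st)[40, 4 * 6 + 1:4], frameValues(fr)[10, ],
               ignore_attr = TRUE)
  # constant rows replicate once lags are in range
  frc <- FrameSequence(matrix(1, 20, 2))
  stc <- stackContext(frc, c(0L, 5L))
  expect_equal(frameValues(stc)[10, ], rep(1, 4), ignore_attr = TRUE)
  expect_error(stackContext(fr, c(5L, 0L)), "sorted")
  expect_error(stackContext(fr, c(0L, -3L)), "sorted|negative")
})

test_that("feature extraction is causal: truncation never changes past frames", {
  set.seed(6)
  x <- matrix(rnorm(800 * 3), 800, 3)
  full <- frameValues(extractHGPower(RawRecording(x)))
  for (n in c(350, 555, 799)) {
    part <- frameValues(extractHGPower(RawRecording(x[seq_len(n), ])))
    T <- nrow(part)
    expect_identical(part, full[seq_len(T), , drop = FALSE])
  }
})
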