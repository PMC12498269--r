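test_that("L1 logistic regression separates a separable session", {
  fx <- fxModels()
  m <- fx$models$logreg
  pred <- labels01(predictOffline(m, fx$frames))
  expect_gte(mean(pred == fx$labels), 0.99)
})

test_that("training inputs are validated", {
  fx <- fxModels()
  one <- list(frames = fx$frames,
              labels = LabelSequence(rep(0L, nFrames(fx$frames))))
  expect_error(trainClassifier(list(one), cfg = trainingConfig("logreg")),
               "single class")
  stacked <- list(frames = stackContext(fx$frames),
                  labels = LabelSequence(fx$labels))
  expect_error(trainClassifier(list(stacked),
                               cfg = trainingConfig("logreg")), "unstacked")
  expect_error(trainClassifier(list(list(frames = fx$frames,
                                         labels = LabelSequence(fx$labels))),
                               val = list(),
                               cfg = trainingConfig("rnn")), "validation")
})

test_that("training is deterministic under a fixed seed", {
  set.seed(1)
  C <- 6; lab <- trialSchedule(3, 200, 80, 40)
  X <- matrix(rnorm(length(lab) * C), ncol = C) + outer(lab, rep(1, C))
  ses <- list(frames = FrameSequence(X, normalized = TRUE),
              labels = LabelSequence(lab))
  for (arch in c("logreg", "cnn", "rnn")) {
    cfg <- trainingConfig(arch, epochs = 1L, seed = 77)
    m1 <- trainClassifier(list(ses), list(ses), cfg)
    m2 <- trainClassifier(list(ses), list(ses), cfg)
    expect_identical(m1@params, m2@params, label = arch)
  }
})

test_that("swapping training classes exactly swaps the predictions", {
  set.seed(2)
  C <- 6; lab <- trialSchedule(3, 200, 80, 40)
  X <- matrix(rnorm(length(lab) * C), ncol = C) + outer(lab, rep(1, C))
  fr <- FrameSequence(X, normalized = TRUE)
  sesA <- list(frames = fr, labels = LabelSequence(lab))
  sesB <- list(frames = fr, labels = LabelSequence(1L - lab))
  for (arch in c("cnn", "rnn")) {
    cfg <- trainingConfig(arch, epochs = 1L, seed = 5)
    mA <- trainClassifier(list(sesA), list(sesA), cfg)
    mB <- trainClassifier(list(sesB), list(sesB), cfg)
    pA <- labels01(predictOffline(mA, fr))
    pB <- labels01(predictOffline(mB, fr))
    expect_identical(pA, 1L - pB, label = arch)
  }
})

test_that("the RNN keeps the best-validation epoch and carries state", {
  fx <- fxModels()
  m <- fx$models$rnn
  log <- m@trainingLog
  expect_lte(min(log$valLoss), log$valLoss[1])
  # resetting recurrent state mid-sequence changes subsequent outputs
  X <- frameValues(fx$frames)
  st <- freshState(m)
  for (t in 1:60) st <- predictStep(m, X[t, ], st)$state
  contin <- predictStep(m, X[61, ], st)
  reset <- predictStep(m, X[61, ], freshState(m))
  expect_false(identical(st$h2, freshState(m)$h2))
  p1 <- numeric(0); p2 <- numeric(0)
  s1 <- contin$state; s2 <- reset$state
  for (t in 62:80) {
    r1 <- predictStep(m, X[t, ], s1); s1 <- r1$state
    r2 <- predictStep(m, X[t, ], s2); s2 <- r2$state
    p1 <- c(p1, r1$class); p2 <- c(p2, r2$class)
  }
  expect_false(identical(s1$h2, s2$h2))
})

test_that("folding predictStep reproduces predictOffline for every arch", {
  fx <- fxModels()
  X <- frameValues(fx$frames)
  for (arch in names(fx$models)) {
    m <- fx$models[[arch]]
    off <- labels01(predictOffline(m, fx$frames))
    st <- freshState(m)
    out <- integer(nrow(X))
    for (t in seq_len(nrow(X))) {
      r <- predictStep(m, X[t, ], st)
      out[t] <- r$class
      st <- r$state
    }
    expect_identical(out, off, label = arch)
  }
  # empty sequence
  empty <- FrameSequence(matrix(0, 0, 8), normalized = TRUE)
  expect_equal(nFrames(predictOffline(fx$models$logreg, empty)), 0L)
})

test_that("prediction validates its inputs", {
  fx <- fxModels()
  m <- fx$models$logreg
  expect_error(predictStep(m, rnorm(3)), "dimension")
  expect_error(predictStep(m, rnorm(8), freshState(fx$models$rnn)),
               "architecture")
  raw <- FrameSequence(frameValues(fx$frames), normalized = FALSE)
  expect_warning(predictOffline(m, raw), "normalized|z-scored")
  expect_error(predictOffline(m, stackContext(fx$frames)), "unstacked")
})
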