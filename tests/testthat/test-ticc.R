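test_that("window embedding dilates past frames into layers", {
  set.seed(1)
  fr <- FrameSequence(matrix(rnorm(60 * 3), 60, 3))
  expect_identical(windowEmbed(fr, 1L), fr)
  # w = 5, d = 5: 200 ms of context; w = 7: 300 ms, D = 7C
  e5 <- windowEmbed(fr, 5L, 5L)
  expect_equal(ncol(frameValues(e5)), 15L)
  expect_equal(max(e5@stackLags), 20L)  # 4*5 frames = 200 ms at 10 ms
  e7 <- windowEmbed(fr, 7L, 5L)
  expect_equal(ncol(frameValues(e7)), 21L)
  expect_equal(max(e7@stackLags), 30L)  # 300 ms
  # layer j of row t is frame t - (j-1)*d: layer 2 of row 30 is frame 25
  expect_equal(frameValues(e5)[30, 4:6], frameValues(fr)[25, ],
               ignore_attr = TRUE)
  expect_equal(frameValues(e5)[30, 7:9], frameValues(fr)[20, ],
               ignore_attr = TRUE)
})

test_that("cluster negative log-likelihood matches the Gaussian closed form", {
  d <- 5
  cl <- neurovad:::makeMRFCluster(rep(0, d), diag(d), 10L, 1L, d)
  # x = mu, identity precision
  expect_equal(clusterNLL(rep(0, d), cl), 0.5 * d * log(2 * pi))
  # scaling the precision by 4 lowers the NLL by d/2 log 4 at x = mu
  cl4 <- neurovad:::makeMRFCluster(rep(0, d), 4 * diag(d), 10L, 1L, d)
  expect_equal(clusterNLL(rep(0, d), cl) - clusterNLL(rep(0, d), cl4),
               0.5 * d * log(4))
  # grows quadratically with distance
  n1 <- clusterNLL(rep(1, d), cl)
  n2 <- clusterNLL(rep(2, d), cl)
  expect_equal(n2 - clusterNLL(rep(0, d), cl),
               4 * (n1 - clusterNLL(rep(0, d), cl)))
  expect_error(clusterNLL(rep(0, d + 1), cl), "dimension")
})

test_that("dynamic-programming assignment is exact and respects beta limits", {
  set.seed(11)
  mkModel <- function(K, d) {
    cls <- lapply(seq_len(K), function(k)
      neurovad:::makeMRFCluster(rnorm(d), crossprod(matrix(rnorm(d * d),
                                                           d)) + diag(d),
                                1L, 1L, d))
    new("TICCModel", clusters = cls, hyper = unclass(ticcHyperparams(K = K)),
        objectiveTrace = numeric(), converged = TRUE, nIter = 1L)
  }
  d <- 3
  fr <- FrameSequence(matrix(rnorm(12 * d), 12, d))
  model <- mkModel(2, d)
  nll <- neurovad:::nllMatrix(frameValues(fr), model@clusters)

  # beta = 0: independent per-frame argmin
  m0 <- model; m0@hyper$beta <- 0
  expect_equal(labels01(estepAssign(fr, m0)), max.col(-nll) - 1L)

  # very large beta: constant path using the lowest-total-NLL cluster
  mB <- model; mB@hyper$beta <- 1e9
  labB <- labels01(estepAssign(fr, mB))
  expect_equal(length(unique(labB)), 1L)
  expect_equal(labB[1], which.min(colSums(nll)) - 1L)

  # exhaustive-search oracle at beta = 50
  m50 <- model; m50@hyper$beta <- 50
  lab <- labels01(estepAssign(fr, m50))
  oracle <- oracleBestPath(nll, 50)
  expect_equal(pathCost(nll, lab, 50), oracle$cost, tolerance = 1e-10)
  if (oracle$nMinimizers == 1) expect_equal(lab, oracle$path)
})

test_that("label switches are non-increasing in the switching penalty", {
  set.seed(12)
  d <- 4
  fr <- FrameSequence(matrix(rnorm(400 * d), 400, d) +
                        outer(trialSchedule(4, 100, 40, 20), rep(1, d)))
  cls <- lapply(0:1, function(k)
    neurovad:::makeMRFCluster(rep(k, d), diag(d), 1L, 1L, d))
  model <- new("TICCModel", clusters = cls,
               hyper = unclass(ticcHyperparams()),
               objectiveTrace = numeric(), converged = TRUE, nIter = 1L)
  switches <- vapply(c(0, 5, 50, 500), function(b) {
    model@hyper$beta <- b
    l <- labels01(estepAssign(fr, model))
    sum(l[-1] != l[-length(l)])
  }, numeric(1))
  expect_true(all(diff(switches) <= 0))
})

test_that("M-step solves the Toeplitz graphical lasso", {
  set.seed(13)
  # lam = 0, w = 1: converges toward the true inverse covariance with n
  d <- 4
  theta <- crossprod(matrix(rnorm(d * d), d)) / d + diag(d)
  R <- chol(solve(theta))
  err <- vapply(c(1e3, 1e4), function(n) {
    X <- matrix(rnorm(n * d), n, d) %*% R
    fr <- FrameSequence(X)
    lab <- LabelSequence(integer(n), classes = character())
    cl <- mstepUpdate(fr, lab, lam = 0)
    norm(precisionMatrix(cl[[1]]) - theta, "F")
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.25)

  # very large lam: exact zeros off the diagonal
  X <- matrix(rnorm(500 * d), 500, d)
  cl <- mstepUpdate(FrameSequence(X),
                    LabelSequence(integer(500), classes = character()),
                    lam = 50)
  P <- precisionMatrix(cl[[1]])
  expect_identical(P[row(P) != col(P)], rep(0, d * d - d))

  # w = 2 on i.i.d.-in-time data: cross-time blocks shrink faster
  X2 <- matrix(rnorm(3000 * 3), 3000, 3) %*% chol(solve(
    crossprod(matrix(rnorm(9), 3)) / 3 + diag(3)))
  emb <- windowEmbed(FrameSequence(X2), 2L, 1L)
  cl2 <- mstepUpdate(emb, LabelSequence(integer(3000),
                                        classes = character()),
                     lam = 0.05, nLayers = 2L)
  P2 <- precisionMatrix(cl2[[1]])
  within <- P2[1:3, 1:3]; cross <- P2[1:3, 4:6]
  expect_lt(mean(abs(cross)), mean(abs(within - diag(diag(within)))) + 0.05)
  expect_lt(mean(abs(cross)), 0.05)
})

test_that("M-step output always satisfies the MRF invariants", {
  set.seed(14)
  for (i in 1:6) {
    w <- sample(1:3, 1); C <- sample(2:4, 1)
    n <- 400
    X <- matrix(rnorm(n * C), n, C)
    emb <- windowEmbed(FrameSequence(X), w, 2L)
    lab <- LabelSequence(sample(0:1, n, TRUE), classes = character())
    cls <- mstepUpdate(emb, lab, lam = runif(1, 0, 0.1), nLayers = w)
    for (cl in cls) {
      P <- precisionMatrix(cl)
      expect_lt(max(abs(P - t(P))), 1e-8)
      expect_gt(min(eigen(P, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
      for (bi in seq_len(w - 1)) for (bj in seq_len(w - 1)) {
        b1 <- P[((bi - 1) * C + 1):(bi * C), ((bj - 1) * C + 1):(bj * C)]
        b2 <- P[(bi * C + 1):((bi + 1) * C), (bj * C + 1):((bj + 1) * C)]
        expect_lt(max(abs(b1 - b2)), 1e-8)
      }
    }
  }
  expect_error(mstepUpdate(FrameSequence(matrix(rnorm(20), 10, 2)),
                           LabelSequence(c(rep(0L, 9), 1L),
                                         classes = character()), 0.1),
               "fewer than 2")
})

test_that("GMM initialization recovers well-separated blobs deterministically", {
  set.seed(15)
  X <- rbind(matrix(rnorm(300 * 2), ncol = 2),
             matrix(rnorm(300 * 2, mean = 8), ncol = 2))
  truth <- rep(0:1, each = 300)
  fr <- FrameSequence(X)
  lab <- labels01(gmmInitialize(fr, 2, seed = 9))
  acc <- max(mean(lab == truth), mean(1L - lab == truth))
  expect_gte(acc, 0.99)
  # determinism
  expect_identical(lab, labels01(gmmInitialize(fr, 2, seed = 9)))
  # K = 1: all zero
  expect_identical(labels01(gmmInitialize(fr, 1)), integer(600))
})

test_that("fitTICC converges, descends its objective, and is equivariant", {
  ses <- fxFeatureSession()
  hp <- ticcHyperparams(seed = 1)
  fit <- fitTICC(ses$frames, hp)
  expect_true(fit$model@converged)
  tr <- objectiveTrace(fit$model)
  expect_true(traceDescends(tr))
  # determinism
  fit2 <- fitTICC(ses$frames, hp)
  expect_identical(labels01(fit$labels), labels01(fit2$labels))
  # K = 1 converges immediately to a single cluster
  f1 <- fitTICC(ses$frames, ticcHyperparams(K = 1))
  expect_equal(f1$model@nIter, 1L)
  expect_true(all(labels01(f1$labels) == 0L))
  # recovery on well-separated MRFs at defaults
  lab <- labels01(fit$labels)
  acc <- max(mean(lab == ses$schedule), mean(1L - lab == ses$schedule))
  expect_gte(acc, 0.90)
})

test_that("cluster-order permutation permutes the assignment consistently", {
  ses <- fxFeatureSession()
  fit <- fitTICC(ses$frames, ticcHyperparams(seed = 1))
  model <- fit$model
  emb <- ses$frames
  lab <- labels01(estepAssign(emb, model))
  swapped <- model
  swapped@clusters <- rev(model@clusters)
  labS <- labels01(estepAssign(emb, swapped))
  expect_equal(labS, 1L - lab)
})
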