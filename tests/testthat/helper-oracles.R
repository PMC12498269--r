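# Independent oracles used to cross-check the package's implementations.
# Each is written against the textbook definition, not the package code.

# Levenshtein distance, row-vectorized textbook DP. The within-row
# dependency (insertions) is resolved exactly by a cumulative minimum:
# cur[j] = min_k<=j ( m[k] + (j - k) ).
oracleLevenshtein <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    sub <- prev[1:m] + (a[i] != b)
    del <- prev[2:(m + 1)] + 1
    cand <- pmin(sub, del)
    prev <- cummin(c(i, cand) - 0:m) + 0:m
  }
  prev[m + 1]
}

# Exhaustive minimum-cost label path: enumerates all K^T sequences by
# growing the full cost vector one time step at a time (sequence digits in
# base K, time step 1 least significant).
oracleBestPath <- function(nll, beta) {
  T <- nrow(nll); K <- ncol(nll)
  v <- nll[1, ]
  last <- 0:(K - 1)
  if (T > 1) for (t in 2:T) {
    nOld <- length(v)
    v <- rep(v, times = K) + rep(nll[t, ], each = nOld) +
      beta * (rep(last, times = K) != rep(0:(K - 1), each = nOld))
    last <- rep(0:(K - 1), each = nOld)
  }
  best <- which.min(v)
  minCost <- v[best]
  decode <- function(i) {
    i <- i - 1L
    out <- integer(T)
    for (t in seq_len(T)) {
      out[t] <- i %% K
      i <- i %/% K
    }
    out
  }
  list(cost = minCost, path = decode(best),
       nMinimizers = sum(v <= minCost + 1e-12))
}

pathCost <- function(nll, lab, beta) {
  sum(nll[cbind(seq_along(lab), lab + 1L)]) +
    beta * sum(lab[-1] != lab[-length(lab)])
}

# Pair of well-separated block-Toeplitz precisions with disjoint
# off-diagonal supports (the cluster-recovery ground truth).
disjointPrecisionPair <- function(C, density = 0.4, strength = 1.5,
                                  seed = 1, minEigen = 0.1) {
  set.seed(seed)
  up <- sample(which(upper.tri(diag(C))))
  half <- floor(length(up) / 2)
  mk <- function(idx) {
    b <- diag(C)
    on <- idx[stats::runif(length(idx)) < density]
    b[on] <- stats::runif(length(on), strength / 2, strength) *
      sample(c(-1, 1), length(on), replace = TRUE)
    b <- b + t(b) - diag(diag(b))
    ev <- min(eigen(b, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < minEigen) b <- b + (minEigen - ev) * diag(C)
    b
  }
  list(speech = mk(up[1:half]), nonspeech = mk(up[(half + 1):length(up)]))
}

randomBinaryLabels <- function(n, p = 0.3) {
  LabelSequence(as.integer(stats::runif(n) < p))
}

# Objective descent check: the EM trace may only rise across an
# empty-cluster restart (marked on the trace).
traceDescends <- function(tr, tol = 1e-6) {
  if (length(tr) < 2) return(TRUE)
  resc <- attr(tr, "rescues")
  if (is.null(resc)) resc <- integer(0)
  d <- diff(tr)
  bad <- which(d > tol * pmax(abs(tr[-length(tr)]), 1)) + 1L
  all(bad %in% resc)
}
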