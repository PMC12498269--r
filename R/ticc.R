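#' TICC hyperparameters
#'
#' Hyperparameters of Toeplitz Inverse Covariance-based Clustering. The
#' defaults (K = 2 clusters, switching penalty beta = 50, sparsity
#' lambda = 11e-4, single-layer MRFs, 5-frame dilation between layers) are
#' the reference configuration for speech/non-speech segmentation of
#' high-gamma frames.
#'
#' @param K number of clusters.
#' @param beta switching penalty added when consecutive frames change
#'   cluster (>= 0).
#' @param lam L1 sparsity penalty on the MRF precision matrices (>= 0).
#' @param nLayers number of Toeplitz layers w (1 = no temporal context;
#'   5 layers reach 200 ms and 7 layers 300 ms into the past at the default
#'   dilation).
#' @param dilationFrames spacing between consecutive layers in frames
#'   (5 frames = 50 ms, skipping the 40 ms window overlap).
#' @param maxIter maximum EM iterations.
#' @param seed integer seed (GMM initialization).
#' @return A validated list of class \code{"ticcHyperparams"}.
#' @export
ticcHyperparams <- function(K = 2L, beta = 50, lam = 11e-4, nLayers = 1L,
                            dilationFrames = 5L, maxIter = 100L, seed = 1L) {
  hp <- list(K = as.integer(K), beta = beta, lam = lam,
             nLayers = as.integer(nLayers),
             dilationFrames = as.integer(dilationFrames),
             maxIter = as.integer(maxIter), seed = as.integer(seed))
  if (hp$K < 1) stop("K must be >= 1")
  if (hp$beta < 0 || hp$lam < 0) stop("beta and lam must be >= 0")
  if (hp$nLayers < 1) stop("nLayers must be >= 1")
  class(hp) <- "ticcHyperparams"
  hp
}

#' Dilated window embedding
#'
#' Builds the per-frame observation of a w-layer MRF: row t concatenates
#' the frames (x_t, x_(t-d), ..., x_(t-(w-1)d)) with zero-filling where the
#' lag reaches before the sequence start. With the default dilation of 5
#' frames, 5 layers reach 200 ms and 7 layers 300 ms into the past.
#' \code{nLayers = 1} returns the input unchanged.
#'
#' @param frames a \linkS4class{FrameSequence}.
#' @param nLayers number of layers w (>= 1).
#' @param dilationFrames spacing d between layers, in frames.
#' @return A \linkS4class{FrameSequence} with D multiplied by w.
#' @export
windowEmbed <- function(frames, nLayers = 1L, dilationFrames = 5L) {
  stopifnot(is(frames, "FrameSequence"), nLayers >= 1)
  if (nLayers == 1L) return(frames)
  stackContext(frames, lagsFrames = (seq_len(nLayers) - 1L) * dilationFrames)
}

#' Gaussian-mixture initial assignment
#'
#' Hard per-frame assignments from a K-component full-covariance Gaussian
#' mixture, used as iteration-0 alignment for the TICC algorithm. Model
#' selection is bypassed (fixed K); the fit is seeded and deterministic.
#' Degenerate fits (empty components) trigger a bounded number of re-seeded
#' retries.
#'
#' @param embedded an embedded \linkS4class{FrameSequence}.
#' @param K number of components.
#' @param seed integer seed.
#' @param maxRetries retries on degenerate fits.
#' @return A \linkS4class{LabelSequence} with labels 0..K-1.
#' @importFrom mclust Mclust mclustBIC
#' @export
gmmInitialize <- function(embedded, K, seed = 1L, maxRetries = 5L) {
  stopifnot(is(embedded, "FrameSequence"), K >= 1)
  X <- embedded@values
  T <- nrow(X)
  mkLabels <- function(l) LabelSequence(
    l, frameShift = embedded@frameShift, startTime = embedded@startTime,
    classes = setNames(paste("cluster", seq_len(max(l + 1L)) - 1L),
                       seq_len(max(l + 1L)) - 1L))
  if (K == 1L) return(mkLabels(integer(T)))
  if (T <= K * ncol(X))
    warning("fewer frames than K * dimension; GMM fit may be unstable")
  for (att in seq_len(maxRetries)) {
    set.seed(seed + att - 1L)
    sub <- sort(sample.int(T, min(T, 1000L)))
    fit <- tryCatch(
      mclust::Mclust(X, G = K, modelNames = "VVV", verbose = FALSE,
                     initialization = list(subset = sub)),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$classification)) == K)
      return(mkLabels(as.integer(fit$classification) - 1L))
  }
  stop("GMM initialization degenerate after ", maxRetries, " retries")
}

## ---- Toeplitz equivalence classes -----------------------------------------

.toeplitzCache <- new.env(parent = emptyenv())

# Equivalence classes of matrix entries tied by the block-Toeplitz +
# symmetry constraint: entry in sub-block (p, q) at channel pair (c1, c2)
# belongs to the class of (lag = q - p, c1, c2), merged with its transpose
# (-lag, c2, c1). Diagonal classes (lag 0, c1 == c2) are unpenalized.
toeplitzGroups <- function(w, C) {
  key <- paste(w, C, sep = "x")
  if (!is.null(.toeplitzCache[[key]])) return(.toeplitzCache[[key]])
  d <- w * C
  ii <- rep(seq_len(d), times = d)
  jj <- rep(seq_len(d), each = d)
  p <- (ii - 1L) %/% C
  q <- (jj - 1L) %/% C
  c1 <- (ii - 1L) %% C + 1L
  c2 <- (jj - 1L) %% C + 1L
  s <- q - p
  a1 <- ifelse(s > 0, c1, ifelse(s < 0, c2, pmin(c1, c2)))
  a2 <- ifelse(s > 0, c2, ifelse(s < 0, c1, pmax(c1, c2)))
  gkey <- abs(s) * C * C + (a1 - 1L) * C + a2
  classId <- as.integer(factor(gkey))
  G <- max(classId)
  sizes <- tabulate(classId, G)
  pen <- !(s == 0L & c1 == c2)
  penGroup <- as.logical(rowsum(as.numeric(pen), classId)[, 1] > 0)
  out <- list(classId = classId, sizes = sizes, penalized = penGroup, d = d)
  .toeplitzCache[[key]] <- out
  out
}

# Project a matrix onto the Toeplitz-symmetric set (group averaging),
# soft-thresholding penalized groups: the exact prox of
# lam*||.||_1,off + indicator(Toeplitz) under the ADMM quadratic.
toeplitzProx <- function(A, groups, lamOverRho) {
  gm <- rowsum(as.vector(A), groups$classId)[, 1] / groups$sizes
  zg <- ifelse(groups$penalized, softThreshold(gm, lamOverRho), gm)
  matrix(zg[groups$classId], groups$d, groups$d)
}

## ---- single-cluster Toeplitz graphical lasso (ADMM) -----------------------

# minimize -log det Theta + tr(S Theta) + lam * ||Theta||_1,off
# over symmetric PD block-Toeplitz matrices. Alternates an eigenvalue-based
# log-det proximal step with the group-averaging/soft-threshold projection.
toeplitzGlasso <- function(S, lam, w, C, rho = 1, maxIter = 1000L,
                           absTol = 1e-6, relTol = 1e-4) {
  d <- nrow(S)
  groups <- toeplitzGroups(w, C)
  Z <- diag(1 / pmax(diag(S), 1e-8))
  U <- matrix(0, d, d)
  frob <- function(M) sqrt(sum(M * M))
  for (it in seq_len(maxIter)) {
    A <- rho * (Z - U) - S
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    ev <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    Theta <- e$vectors %*% (ev * t(e$vectors))
    Zold <- Z
    Z <- toeplitzProx(Theta + U, groups, lam / rho)
    U <- U + Theta - Z
    r <- frob(Theta - Z)
    sres <- rho * frob(Z - Zold)
    epsPri <- d * absTol + relTol * max(frob(Theta), frob(Z))
    epsDual <- d * absTol + relTol * frob(rho * U)
    if (r < epsPri && sres < epsDual) {
      return(finalizeToeplitzPrecision(Z))
    }
  }
  stop(sprintf(
    "ADMM did not converge in %d iterations (primal %.3g/%.3g, dual %.3g/%.3g)",
    maxIter, r, epsPri, sres, epsDual))
}

# Z is exactly Toeplitz-symmetric and sparse; nudge onto the PD cone if a
# small eigenvalue slipped below zero (preserves Toeplitz structure).
finalizeToeplitzPrecision <- function(Z, minEigen = 1e-8) {
  Z <- (Z + t(Z)) / 2
  ev <- eigen(Z, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < minEigen) Z <- Z + (minEigen - min(ev)) * diag(nrow(Z))
  Z
}

makeMRFCluster <- function(mu, theta, nAssigned, w, C) {
  ld <- 2 * sum(log(diag(chol(theta))))  # chol errors if not PD
  new("MRFCluster", mean = as.numeric(mu), precision = theta,
      logDet = ld, nAssigned = as.integer(nAssigned),
      nLayers = as.integer(w), nChannels = as.integer(C))
}

#' Gaussian negative log-likelihood under an MRF cluster
#'
#' \code{0.5 * ((x - mu)' Theta (x - mu) - log det Theta + d log 2 pi)}.
#'
#' @param observation numeric vector of dimension w*C.
#' @param cluster an \linkS4class{MRFCluster}.
#' @return the negative log-likelihood (a single number).
#' @export
clusterNLL <- function(observation, cluster) {
  stopifnot(is(cluster, "MRFCluster"))
  d <- length(cluster@mean)
  if (length(observation) != d) stop("dimension mismatch")
  r <- observation - cluster@mean
  0.5 * (drop(r %*% cluster@precision %*% r) - cluster@logDet +
           d * log(2 * pi))
}

# T x K matrix of per-frame NLLs, vectorized over frames.
nllMatrix <- function(X, clustersList) {
  T <- nrow(X); K <- length(clustersList)
  out <- matrix(0, T, K)
  for (k in seq_len(K)) {
    cl <- clustersList[[k]]
    d <- length(cl@mean)
    Xc <- sweep(X, 2, cl@mean)
    q <- rowSums((Xc %*% cl@precision) * Xc)
    out[, k] <- 0.5 * (q - cl@logDet + d * log(2 * pi))
  }
  out
}

#' Dynamic-programming cluster assignment (E-step)
#'
#' Finds the label path minimizing the total negative log-likelihood plus
#' \code{beta} per switch between consecutive frames, by a forward dynamic
#' program with backtracking. Ties break toward the lower cluster index.
#' With \code{beta = 0} every frame is assigned independently to its
#' per-frame argmin.
#'
#' @param embedded an embedded \linkS4class{FrameSequence}.
#' @param model a \linkS4class{TICCModel} (its clusters and beta are used).
#' @return A \linkS4class{LabelSequence} of cluster IDs 0..K-1.
#' @export
estepAssign <- function(embedded, model) {
  stopifnot(is(embedded, "FrameSequence"), is(model, "TICCModel"))
  nll <- nllMatrix(embedded@values, model@clusters)
  lab <- viterbi_assign_cpp(nll, model@hyper$beta)
  K <- length(model@clusters)
  LabelSequence(lab, frameShift = embedded@frameShift,
                startTime = embedded@startTime,
                classes = setNames(paste("cluster", seq_len(K) - 1L),
                                   seq_len(K) - 1L))
}

#' Toeplitz-constrained cluster update (M-step)
#'
#' Per cluster: the mean is the average of assigned frames; the precision
#' solves the graphical-lasso problem
#' \code{-log det Theta + tr(S Theta) + lam ||Theta||_1,off} over symmetric
#' positive-definite block-Toeplitz matrices via ADMM (eigenvalue-based
#' log-det step alternating with group-averaging + soft-thresholding onto
#' the Toeplitz set).
#'
#' @param embedded an embedded \linkS4class{FrameSequence} (D = w*C).
#' @param labels a \linkS4class{LabelSequence} of cluster IDs 0..K-1; every
#'   cluster must have at least 2 assigned frames.
#' @param lam L1 penalty applied as given.
#' @param nLayers number of Toeplitz layers w (divides D).
#' @param scaleByCluster if TRUE, the penalty used for cluster k is
#'   \code{2 * lam / n_k}, the scaling under which the EM objective of
#'   \code{\link{fitTICC}} is exactly non-increasing.
#' @param rho ADMM penalty parameter.
#' @param diagLoad diagonal loading added to each empirical covariance.
#' @param maxIterAdmm,absTol,relTol ADMM stopping controls.
#' @return list of \linkS4class{MRFCluster}, one per cluster ID present.
#' @export
mstepUpdate <- function(embedded, labels, lam, nLayers = 1L,
                        scaleByCluster = FALSE, rho = 1, diagLoad = 1e-6,
                        maxIterAdmm = 1000L, absTol = 1e-6, relTol = 1e-4) {
  stopifnot(is(embedded, "FrameSequence"), is(labels, "LabelSequence"))
  X <- embedded@values
  lab <- labels@labels
  if (length(lab) != nrow(X)) stop("labels and frames disagree in length")
  w <- as.integer(nLayers)
  D <- ncol(X)
  if (D %% w != 0) stop("feature dimension not divisible by nLayers")
  C <- D %/% w
  K <- max(lab) + 1L
  out <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(lab == k - 1L)
    if (length(idx) < 2)
      stop("cluster ", k - 1L, " has fewer than 2 assigned frames")
    Xi <- X[idx, , drop = FALSE]
    mu <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mu)
    S <- crossprod(Xc) / nrow(Xc) + diagLoad * diag(D)
    lamk <- if (scaleByCluster) 2 * lam / length(idx) else lam
    theta <- toeplitzGlasso(S, lamk, w, C, rho = rho,
                            maxIter = maxIterAdmm, absTol = absTol,
                            relTol = relTol)
    out[[k]] <- makeMRFCluster(mu, theta, length(idx), w, C)
  }
  out
}

# Global TICC objective: total NLL under the assignment + switching cost +
# lambda * off-diagonal L1 of all precisions (the quantity the EM
# alternation descends when the M-step penalty is scaled by 2*lam/n_k).
ticcObjective <- function(nll, lab, clustersList, beta, lam) {
  tot <- sum(nll[cbind(seq_along(lab), lab + 1L)])
  sw <- sum(lab[-1] != lab[-length(lab)])
  l1 <- sum(vapply(clustersList, function(cl) {
    P <- cl@precision
    sum(abs(P)) - sum(abs(diag(P)))
  }, numeric(1)))
  tot + beta * sw + lam * l1
}

# Reassign the worst-fitting 1% of frames (at least minFrames) to clusters
# that fell below the minimum size: the standard EM restart trick keeping K
# fixed.
rescueSmallClusters <- function(lab, nll, K, minFrames) {
  counts <- tabulate(lab + 1L, K)
  small <- which(counts < minFrames) - 1L
  if (!length(small)) return(list(labels = lab, rescued = FALSE))
  fit <- nll[cbind(seq_along(lab), lab + 1L)]
  nTake <- max(minFrames, ceiling(0.01 * length(lab)))
  for (k in small) {
    avail <- which(!(lab %in% small))
    nEff <- min(nTake, max(0L, length(avail) - minFrames))
    if (nEff < 1L)
      stop("cannot refill cluster ", k, ": not enough frames to reassign")
    take <- avail[order(fit[avail], decreasing = TRUE)][seq_len(nEff)]
    lab[take] <- k
    fit[take] <- -Inf  # not taken again for another empty cluster
  }
  list(labels = lab, rescued = TRUE)
}

#' Fit Toeplitz Inverse Covariance-based Clustering
#'
#' EM-style alternation: dynamic-programming assignment with switching
#' penalty beta (\code{\link{estepAssign}}) against Toeplitz-constrained
#' sparse inverse-covariance updates (\code{\link{mstepUpdate}}), started
#' from a Gaussian-mixture assignment, until the assignment is stationary
#' or \code{maxIter} is reached. Clusters that fall below the minimum size
#' (\code{max(20, w*C/10)} frames) are refilled with the worst-fitting 1\%
#' of frames; persistent emptiness is an error.
#'
#' @param frames a \linkS4class{FrameSequence} (unembedded; the w-layer
#'   dilated embedding is applied internally).
#' @param hyper a \code{\link{ticcHyperparams}}.
#' @return list with \code{model} (\linkS4class{TICCModel}) and
#'   \code{labels} (\linkS4class{LabelSequence} on the original frames).
#' @export
fitTICC <- function(frames, hyper = ticcHyperparams()) {
  stopifnot(is(frames, "FrameSequence"), inherits(hyper, "ticcHyperparams"))
  embedded <- windowEmbed(frames, hyper$nLayers, hyper$dilationFrames)
  X <- embedded@values
  T <- nrow(X)
  Cbase <- ncol(frames@values)
  K <- hyper$K
  minFrames <- max(20L, (hyper$nLayers * Cbase) %/% 10L)
  if (T < minFrames * K)
    stop("too few frames (", T, ") for K = ", K, " clusters")
  labSeq <- gmmInitialize(embedded, K, seed = hyper$seed)
  lab <- labSeq@labels
  # refill degenerate initial clusters from the largest one (seeded)
  counts <- tabulate(lab + 1L, K)
  if (any(counts < minFrames)) {
    set.seed(hyper$seed)
    for (k in which(counts < minFrames) - 1L) {
      big <- which.max(tabulate(lab + 1L, K)) - 1L
      lab[sample(which(lab == big), minFrames)] <- k
    }
  }
  trace <- numeric(0)
  rescues <- integer(0)
  converged <- FALSE
  consecRescue <- 0L
  clustersList <- NULL
  it <- 0L
  while (it < hyper$maxIter) {
    it <- it + 1L
    labNow <- LabelSequence(lab, frameShift = embedded@frameShift,
                            classes = character())
    clustersList <- mstepUpdate(embedded, labNow, lam = hyper$lam,
                                nLayers = hyper$nLayers,
                                scaleByCluster = TRUE)
    nll <- nllMatrix(X, clustersList)
    trace <- c(trace, ticcObjective(nll, lab, clustersList, hyper$beta,
                                    hyper$lam))
    newLab <- as.integer(viterbi_assign_cpp(nll, hyper$beta))
    res <- rescueSmallClusters(newLab, nll, K, minFrames)
    newLab <- res$labels
    if (res$rescued) rescues <- c(rescues, it + 1L)
    consecRescue <- if (res$rescued) consecRescue + 1L else 0L
    if (consecRescue >= 5L)
      stop("a cluster remained empty for 5 consecutive iterations")
    if (identical(newLab, lab)) { converged <- TRUE; break }
    lab <- newLab
  }
  model <- new("TICCModel", clusters = clustersList, hyper = unclass(hyper),
               objectiveTrace = trace,
               rescueIterations = rescues[rescues <= it],
               converged = converged, nIter = it)
  labels <- LabelSequence(lab, frameShift = frames@frameShift,
                          startTime = frames@startTime,
                          classes = setNames(paste("cluster", seq_len(K) - 1L),
                                             seq_len(K) - 1L))
  list(model = model, labels = labels)
}

#' Objective trace of a fitted TICC model
#'
#' One objective value per EM iteration (recorded after each M-step). The
#' trace is non-increasing across consecutive iterations except where the
#' empty-cluster restart fired; those iterations are marked in attribute
#' \code{"rescues"}.
#'
#' @param model a \linkS4class{TICCModel}.
#' @return numeric vector with attribute \code{"rescues"}.
#' @export
objectiveTrace <- function(model) {
  stopifnot(is(model, "TICCModel"))
  tr <- model@objectiveTrace
  attr(tr, "rescues") <- model@rescueIterations
  tr
}
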