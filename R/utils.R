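`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats rnorm runif quantile median sd setNames
NULL

## ---- transfer function -> second-order sections ---------------------------

# Pair complex-conjugate (and real) roots into quadratic factors.
splitRootPairs <- function(r) {
  if (!length(r)) return(list())
  tol <- 1e-6
  isreal <- abs(Im(r)) <= tol * pmax(1, Mod(r))
  realr <- sort(Re(r[isreal]))
  crt <- r[!isreal]
  pos <- crt[Im(crt) > 0]
  neg <- crt[Im(crt) < 0]
  if (length(pos) != length(neg) || length(realr) %% 2 != 0)
    stop("roots do not come in conjugate/real pairs")
  pairs <- list()
  for (q in pos[order(-Mod(pos))]) {
    j <- which.min(Mod(neg - Conj(q)))
    pairs[[length(pairs) + 1L]] <- c(q, neg[j])
    neg <- neg[-j]
  }
  # real roots: pair smallest with largest (keeps bandpass zeros at +-1 in
  # the same biquad, giving well-scaled (1, 0, -1) numerators)
  while (length(realr) >= 2) {
    n <- length(realr)
    pairs[[length(pairs) + 1L]] <-
      complex(real = c(realr[1], realr[n]), imaginary = c(0, 0))
    realr <- realr[-c(1, n)]
  }
  pairs
}

quadFromRoots <- function(pr) {
  c(1, -Re(pr[1] + pr[2]), Re(pr[1] * pr[2]))
}

# Convert filter polynomials b(z^-1)/a(z^-1) (equal even order) into a
# cascade of biquads, rows (b0 b1 b2 1 a1 a2). Pole pairs are ordered by
# modulus (closest to the unit circle first) and matched with the nearest
# zero pair.
tf2sos <- function(b, a) {
  b <- as.numeric(b); a <- as.numeric(a)
  k <- b[1] / a[1]
  b <- b / b[1]; a <- a / a[1]
  z <- polyroot(rev(b))
  p <- polyroot(rev(a))
  if (length(z) != length(p))
    stop("tf2sos expects equal numerator and denominator order")
  zp <- splitRootPairs(z)
  pp <- splitRootPairs(p)
  if (length(zp) != length(pp)) stop("unpaired roots in tf2sos")
  pp <- pp[order(-vapply(pp, function(q) max(Mod(q)), numeric(1)))]
  ns <- length(pp)
  sos <- matrix(0, ns, 6)
  for (s in seq_len(ns)) {
    pcur <- pp[[s]]
    d <- vapply(zp, function(q) min(Mod(q[1] - pcur[1]), Mod(q[2] - pcur[1])),
                numeric(1))
    j <- which.min(d)
    sos[s, ] <- c(quadFromRoots(zp[[j]]), quadFromRoots(pcur))
    zp <- zp[-j]
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sosFreqResponse <- function(sos, f, fs) {
  w <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * w + sos[s, 3] * w^2
    den <- 1 + sos[s, 5] * w + sos[s, 6] * w^2
    h <- h * num / den
  }
  h
}

#' High-gamma filter cascade design
#'
#' Designs the two causal 4th-order Butterworth filters of the feature
#' pipeline as second-order-section cascades: a 70-170 Hz band-pass and a
#' 118-122 Hz band-stop attenuating the first line-noise harmonic.
#'
#' @param sampleRate sampling rate in Hz (must exceed 340 Hz).
#' @param band band-pass edges in Hz.
#' @param notch band-stop edges in Hz.
#' @return list with SOS coefficient matrices \code{bandpass} and
#'   \code{bandstop} (rows b0 b1 b2 1 a1 a2).
#' @export
designHGFilters <- function(sampleRate = 1000, band = c(70, 170),
                            notch = c(118, 122)) {
  if (sampleRate < 2 * max(band))
    stop("sampleRate must be at least twice the upper band edge")
  bp <- signal::butter(4, band / (sampleRate / 2), type = "pass")
  bs <- signal::butter(4, notch / (sampleRate / 2), type = "stop")
  list(bandpass = tf2sos(bp$b, bp$a), bandstop = tf2sos(bs$b, bs$a))
}

sosInitState <- function(sos, nChannels) {
  matrix(0, 2 * nrow(sos), nChannels)
}

# Filter a samples x channels matrix through one SOS cascade; state carries
# across calls so chunked filtering is exact.
sosApply <- function(x, sos, state = NULL) {
  if (is.null(state)) state <- sosInitState(sos, ncol(x))
  sos_filter_cpp(x, sos, state)
}

## ---- framing ---------------------------------------------------------------

frameCount <- function(nSamples, windowSamples, shiftSamples) {
  if (nSamples < windowSamples) return(0L)
  as.integer(floor((nSamples - windowSamples) / shiftSamples) + 1L)
}

# Log band power of one complete window (samples x channels). This exact
# function is shared by the offline and streaming paths so both produce
# bit-identical features. epsilon floors silent windows.
windowLogPower <- function(w, eps = 1e-10) {
  log(colMeans(w * w) + eps)
}

## ---- misc ------------------------------------------------------------------

softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Truncated normal by rejection (vectorized, deterministic under set.seed).
rtruncnorm <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1L
    if (guard > 1000L) { out[bad] <- lower; break }
  }
  out
}

# 1/f (pink) noise via spectral shaping; deterministic under set.seed.
pinkNoise <- function(n, nCols = 1) {
  m <- 2^ceiling(log2(max(n, 2)))
  freqs <- c(1, seq_len(m / 2), rev(seq_len(m / 2 - 1)))
  scale <- 1 / sqrt(freqs)
  out <- matrix(0, n, nCols)
  for (j in seq_len(nCols)) {
    wn <- stats::fft(rnorm(m))
    x <- Re(stats::fft(wn * scale, inverse = TRUE)) / m
    x <- x[seq_len(n)]
    out[, j] <- x / sd(x)
  }
  out
}

checkBinaryLabels <- function(x, what = "labels") {
  if (length(x) && !all(x %in% c(0L, 1L)))
    stop(what, " must be binary (0 = non-speech, 1 = speech)")
  invisible(TRUE)
}
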