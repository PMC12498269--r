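# Minimal neural-network engine (dense/conv/pool/LSTM layers, softmax
# cross-entropy, Adam) in base R matrix algebra. Sized for frame-wise
# speech/non-speech classification: inputs are a few hundred features, so
# BLAS-backed matrix products carry the load.

## ---- optimizer -------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

uniformInit <- function(nr, nc, fanIn) {
  matrix(runif(nr * nc, -1, 1) / sqrt(fanIn), nr, nc)
}

## ---- softmax cross-entropy -------------------------------------------------

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# y: integer class indices 1..K. Returns mean CE and gradient wrt logits.
softmaxCE <- function(Z, y) {
  P <- softmaxRows(Z)
  n <- nrow(Z)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-300)))
  dZ <- P
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  list(loss = loss, dZ = dZ / n)
}

## ---- 2D convolution / pooling on a channels x lags grid -------------------
# Activations are stored as (B*P) x M matrices, P = H*W grid positions in
# column-major order, row index (p-1)*B + b. Gathers use precomputed index
# vectors with a trailing all-zero row standing in for padding.

.gridCache <- new.env(parent = emptyenv())

convOffsets <- expand.grid(dr = -1:1, dc = -1:1)

convIdx <- function(H, W, B) {
  key <- paste("c", H, W, B)
  if (!is.null(.gridCache[[key]])) return(.gridCache[[key]])
  P <- H * W
  r <- ((seq_len(P) - 1L) %% H) + 1L
  cc <- ((seq_len(P) - 1L) %/% H) + 1L
  zeroRow <- B * P + 1L
  lst <- vector("list", 9)
  for (o in 1:9) {
    rs <- r + convOffsets$dr[o]
    cs <- cc + convOffsets$dc[o]
    ok <- rs >= 1L & rs <= H & cs >= 1L & cs <= W
    srcp <- (cs - 1L) * H + rs
    base <- rep((srcp - 1L) * B, each = B) + rep_len(seq_len(B), B * P)
    base[!rep(ok, each = B)] <- zeroRow
    lst[[o]] <- base
  }
  out <- list(idx = lst, P = P, zeroRow = zeroRow)
  .gridCache[[key]] <- out
  out
}

poolIdx <- function(H, W, B) {
  key <- paste("p", H, W, B)
  if (!is.null(.gridCache[[key]])) return(.gridCache[[key]])
  H2 <- H %/% 2L; W2 <- W %/% 2L
  P2 <- H2 * W2
  r2 <- ((seq_len(P2) - 1L) %% H2) + 1L
  c2 <- ((seq_len(P2) - 1L) %/% H2) + 1L
  lst <- vector("list", 4)
  o <- 0L
  for (dc in 0:1) for (dr in 0:1) {
    o <- o + 1L
    srcp <- (2L * c2 - 2L + dc) * H + (2L * r2 - 1L + dr)
    lst[[o]] <- rep((srcp - 1L) * B, each = B) + rep_len(seq_len(B), B * P2)
  }
  out <- list(idx = lst, H2 = H2, W2 = W2, P2 = P2)
  .gridCache[[key]] <- out
  out
}

# X: (B*P) x Min. W: list of 9 (Min x Mout) kernels; b: length Mout.
convForward <- function(X, Wk, b, H, W, B) {
  ci <- convIdx(H, W, B)
  Xz <- rbind(X, 0)
  Mout <- ncol(Wk[[1]])
  Z <- matrix(rep(b, each = nrow(X)), nrow(X), Mout)
  for (o in 1:9) Z <- Z + Xz[ci$idx[[o]], , drop = FALSE] %*% Wk[[o]]
  A <- tanh(Z)
  list(A = A, Xz = Xz)
}

convBackward <- function(dA, A, Xz, Wk, H, W, B) {
  ci <- convIdx(H, W, B)
  dZ <- dA * (1 - A * A)
  dZz <- rbind(dZ, 0)
  Min <- ncol(Xz)
  dX <- matrix(0, nrow(dZ), Min)
  dWk <- vector("list", 9)
  for (o in 1:9) {
    dWk[[o]] <- crossprod(Xz[ci$idx[[o]], , drop = FALSE], dZ)
    # transposed conv: gather dZ at the negated offset (index 10 - o)
    dX <- dX + dZz[ci$idx[[10L - o]], , drop = FALSE] %*% t(Wk[[o]])
  }
  list(dX = dX, dW = dWk, db = colSums(dZ))
}

poolForward <- function(X, H, W, B) {
  pi <- poolIdx(H, W, B)
  best <- X[pi$idx[[1]], , drop = FALSE]
  am <- matrix(1L, nrow(best), ncol(best))
  for (j in 2:4) {
    cand <- X[pi$idx[[j]], , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    am[upd] <- j
  }
  list(A = best, argmax = am, H2 = pi$H2, W2 = pi$W2)
}

poolBackward <- function(dA, argmax, H, W, B, nRowsIn) {
  pi <- poolIdx(H, W, B)
  M <- ncol(dA)
  n2 <- nrow(dA)
  dX <- matrix(0, nRowsIn, M)
  for (j in 1:4) {
    sel <- which(argmax == j)
    if (!length(sel)) next
    rows <- ((sel - 1L) %% n2) + 1L
    cols <- ((sel - 1L) %/% n2) + 1L
    dX[cbind(pi$idx[[j]][rows], cols)] <- dA[sel]
  }
  dX
}

# Reshape between (B*P) x M (grid layout) and B x (P*M) (flat layout);
# both directions are pure dim changes on the same column-major vector.
gridToFlat <- function(A, B) { dim(A) <- c(B, length(A) / B); A }
flatToGrid <- function(A, M) { dim(A) <- c(length(A) / M, M); A }

## ---- LeNet-like CNN --------------------------------------------------------
# Input: one frame as a channels (H = C) x lags (W = L) map. Two 3x3
# same-padded conv layers growing the maps by 32 each, each followed by a
# 2x2/stride-2 max pool; then dense layers 128 and 64 and an nOut softmax
# head, tanh activations throughout. The head is zero-initialized so that
# swapping training classes exactly swaps predictions.

cnnInit <- function(C, L, nOut = 2L, maps1 = 32L, maps2 = 64L,
                    fc1 = 128L, fc2 = 64L) {
  H2 <- C %/% 2L; W2 <- L %/% 2L
  H3 <- H2 %/% 2L; W3 <- W2 %/% 2L
  if (H3 < 1L || W3 < 1L)
    stop("input grid ", C, "x", L, " too small for two 2x2 pooling stages")
  flat <- H3 * W3 * maps2
  p <- list()
  for (o in 1:9) p[[paste0("W1_", o)]] <- uniformInit(1L, maps1, 9)
  p$b1 <- numeric(maps1)
  for (o in 1:9) p[[paste0("W2_", o)]] <- uniformInit(maps1, maps2, 9 * maps1)
  p$b2 <- numeric(maps2)
  p$Wf1 <- uniformInit(flat, fc1, flat)
  p$bf1 <- numeric(fc1)
  p$Wf2 <- uniformInit(fc1, fc2, fc1)
  p$bf2 <- numeric(fc2)
  p$Wout <- matrix(0, fc2, nOut)
  p$bout <- numeric(nOut)
  attr(p, "geom") <- list(C = C, L = L, H2 = H2, W2 = W2, H3 = H3, W3 = W3,
                          maps1 = maps1, maps2 = maps2, flat = flat)
  p
}

cnnForward <- function(p, X, B) {
  g <- attr(p, "geom")
  W1 <- lapply(1:9, function(o) p[[paste0("W1_", o)]])
  W2 <- lapply(1:9, function(o) p[[paste0("W2_", o)]])
  # X: B x (C*L) frame rows -> grid layout (B*P) x 1
  Xg <- matrix(as.vector(X), B * g$C * g$L, 1L)
  c1 <- convForward(Xg, W1, p$b1, g$C, g$L, B)
  p1 <- poolForward(c1$A, g$C, g$L, B)
  c2 <- convForward(p1$A, W2, p$b2, g$H2, g$W2, B)
  p2 <- poolForward(c2$A, g$H2, g$W2, B)
  flat <- gridToFlat(p2$A, B)
  h1 <- tanh(sweep(flat %*% p$Wf1, 2, p$bf1, "+"))
  h2 <- tanh(sweep(h1 %*% p$Wf2, 2, p$bf2, "+"))
  logits <- sweep(h2 %*% p$Wout, 2, p$bout, "+")
  list(logits = logits, c1 = c1, p1 = p1, c2 = c2, p2 = p2, flat = flat,
       h1 = h1, h2 = h2)
}

cnnBackward <- function(p, fw, dLogits, B) {
  g <- attr(p, "geom")
  W1 <- lapply(1:9, function(o) p[[paste0("W1_", o)]])
  W2 <- lapply(1:9, function(o) p[[paste0("W2_", o)]])
  gr <- list()
  gr$Wout <- crossprod(fw$h2, dLogits)
  gr$bout <- colSums(dLogits)
  dh2 <- dLogits %*% t(p$Wout) * (1 - fw$h2^2)
  gr$Wf2 <- crossprod(fw$h1, dh2)
  gr$bf2 <- colSums(dh2)
  dh1 <- dh2 %*% t(p$Wf2) * (1 - fw$h1^2)
  gr$Wf1 <- crossprod(fw$flat, dh1)
  gr$bf1 <- colSums(dh1)
  dflat <- dh1 %*% t(p$Wf1)
  dp2 <- flatToGrid(dflat, g$maps2)
  dc2 <- poolBackward(dp2, fw$p2$argmax, g$H2, g$W2, B, nrow(fw$c2$A))
  bk2 <- convBackward(dc2, fw$c2$A, fw$c2$Xz, W2, g$H2, g$W2, B)
  for (o in 1:9) gr[[paste0("W2_", o)]] <- bk2$dW[[o]]
  gr$b2 <- bk2$db
  dp1 <- poolBackward(bk2$dX, fw$p1$argmax, g$C, g$L, B, nrow(fw$c1$A))
  bk1 <- convBackward(dp1, fw$c1$A, fw$c1$Xz, W1, g$C, g$L, B)
  for (o in 1:9) gr[[paste0("W1_", o)]] <- bk1$dW[[o]]
  gr$b1 <- bk1$db
  gr
}

## ---- LSTM ------------------------------------------------------------------
# Gate order i, f, g, o in the fused 4H projection; forget-gate bias
# initialized to 1. States are 1 x H row matrices.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstmInitLayer <- function(nIn, H) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1
  list(Wx = uniformInit(nIn, 4L * H, nIn), Wh = uniformInit(H, 4L * H, H),
       b = b)
}

# One step; x is 1 x nIn. Shared verbatim by training, offline prediction
# and streaming, which is what makes the three produce identical numbers.
lstmCell <- function(x, h, c, Wx, Wh, b) {
  H <- ncol(h)
  z <- x %*% Wx + h %*% Wh + rep(b, each = 1L)
  i <- sigmoid(z[, 1:H, drop = FALSE])
  f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
  g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
  o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
  cNew <- f * c + i * g
  hNew <- o * tanh(cNew)
  list(h = hNew, c = cNew, i = i, f = f, g = g, o = o)
}

# Forward over a chunk of k frames for one layer; caches gate activations.
lstmChunkForward <- function(X, h0, c0, layer) {
  k <- nrow(X)
  H <- ncol(h0)
  Hs <- matrix(0, k, H); Cs <- matrix(0, k, H)
  Is <- matrix(0, k, H); Fs <- matrix(0, k, H)
  Gs <- matrix(0, k, H); Os <- matrix(0, k, H)
  Hprev <- matrix(0, k, H); Cprev <- matrix(0, k, H)
  Xp <- X %*% layer$Wx
  h <- h0; c <- c0
  for (t in seq_len(k)) {
    Hprev[t, ] <- h; Cprev[t, ] <- c
    z <- Xp[t, , drop = FALSE] + h %*% layer$Wh + rep(layer$b, each = 1L)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c <- f * c + i * g
    h <- o * tanh(c)
    Hs[t, ] <- h; Cs[t, ] <- c
    Is[t, ] <- i; Fs[t, ] <- f; Gs[t, ] <- g; Os[t, ] <- o
  }
  list(H = Hs, C = Cs, I = Is, F = Fs, G = Gs, O = Os,
       Hprev = Hprev, Cprev = Cprev, h = h, c = c, X = X)
}

# Truncated backward over the chunk (state entering the chunk is treated as
# constant). dH: gradient on the layer's hidden outputs.
lstmChunkBackward <- function(cache, dH, layer) {
  k <- nrow(dH); H <- ncol(dH)
  dZ <- matrix(0, k, 4L * H)
  dhNext <- matrix(0, 1L, H)
  dcNext <- matrix(0, 1L, H)
  WhT <- t(layer$Wh)
  for (t in rev(seq_len(k))) {
    dh <- dH[t, , drop = FALSE] + dhNext
    ct <- cache$C[t, , drop = FALSE]
    tc <- tanh(ct)
    o <- cache$O[t, , drop = FALSE]
    dc <- dcNext + dh * o * (1 - tc * tc)
    i <- cache$I[t, , drop = FALSE]
    f <- cache$F[t, , drop = FALSE]
    g <- cache$G[t, , drop = FALSE]
    dzi <- dc * g * i * (1 - i)
    dzf <- dc * cache$Cprev[t, , drop = FALSE] * f * (1 - f)
    dzg <- dc * i * (1 - g * g)
    dzo <- dh * tc * o * (1 - o)
    dz <- cbind(dzi, dzf, dzg, dzo)
    dZ[t, ] <- dz
    dhNext <- dz %*% WhT
    dcNext <- dc * f
  }
  list(dWx = crossprod(cache$X, dZ), dWh = crossprod(cache$Hprev, dZ),
       db = colSums(dZ), dX = dZ %*% t(layer$Wx))
}
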