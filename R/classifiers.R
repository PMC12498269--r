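#' Classifier training configuration
#'
#' Architecture-specific defaults follow the reference setup: the CNN trains
#' with Adam at learning rate 1e-4 for 10 epochs; the LSTM RNN with Adam at
#' 3e-4 for 20 epochs using truncated backpropagation through time with
#' k1 = k2 = 50 frames (0.5 s) and keeps the weights of the epoch with
#' minimum validation loss; the L1 logistic regression is a convex fit with
#' inverse-regularization strength \code{l1Strength}. The logistic
#' regression and CNN consume 7-frame context-stacked input (0 to -300 ms);
#' the RNN consumes unstacked frames and models time itself.
#'
#' @param arch one of \code{"logreg"}, \code{"cnn"}, \code{"rnn"}.
#' @param learningRate Adam learning rate (default per arch).
#' @param epochs training epochs (default per arch).
#' @param tbpttK1,tbpttK2 TBPTT update interval and unroll length in frames
#'   (RNN only).
#' @param l1Strength inverse L1 regularization strength of the logistic
#'   regression (penalty weight 1/(l1Strength * n)).
#' @param batchSize minibatch size (CNN).
#' @param nOut number of output units of the CNN/RNN softmax head.
#' @param hiddenSize LSTM units per layer.
#' @param stackLagsFrames context-stacking lags for logreg/cnn, in frames.
#' @param classWeighting if TRUE, weight classes inversely to frequency
#'   (logreg only; off by default).
#' @param selectBestByVal keep the epoch with minimum validation loss
#'   (default TRUE for rnn, FALSE otherwise).
#' @param seed integer seed; training is deterministic given it.
#' @return list of class \code{"trainingConfig"}.
#' @export
trainingConfig <- function(arch = c("logreg", "cnn", "rnn"),
                           learningRate = NULL, epochs = NULL,
                           tbpttK1 = 50L, tbpttK2 = 50L, l1Strength = 1.0,
                           batchSize = 128L, nOut = 2L, hiddenSize = 100L,
                           stackLagsFrames = seq(0L, 30L, by = 5L),
                           classWeighting = FALSE, selectBestByVal = NULL,
                           seed = 1L) {
  arch <- match.arg(arch)
  learningRate <- learningRate %||% switch(arch, cnn = 1e-4, rnn = 3e-4,
                                           logreg = NA_real_)
  epochs <- epochs %||% switch(arch, cnn = 10L, rnn = 20L, logreg = 1L)
  selectBestByVal <- selectBestByVal %||% (arch == "rnn")
  cfg <- list(arch = arch, learningRate = learningRate,
              epochs = as.integer(epochs), tbpttK1 = as.integer(tbpttK1),
              tbpttK2 = as.integer(tbpttK2), l1Strength = l1Strength,
              batchSize = as.integer(batchSize), nOut = as.integer(nOut),
              hiddenSize = as.integer(hiddenSize),
              stackLagsFrames = as.integer(stackLagsFrames),
              classWeighting = classWeighting,
              selectBestByVal = selectBestByVal, seed = as.integer(seed))
  if (cfg$epochs < 1 || (!is.na(cfg$learningRate) && cfg$learningRate <= 0))
    stop("epochs and learningRate must be positive")
  if (cfg$tbpttK1 < 1 || cfg$tbpttK2 < 1) stop("TBPTT lengths must be >= 1")
  class(cfg) <- "trainingConfig"
  cfg
}

#' Trained frame-wise classifier
#'
#' @slot arch \code{"logreg"}, \code{"cnn"} or \code{"rnn"}.
#' @slot params opaque parameter list.
#' @slot inputSpec list with base feature dimension \code{C} and the
#'   stacking lags applied internally (\code{integer(0)} for the RNN).
#' @slot trainingLog data.frame of per-epoch losses.
#' @slot seed the training seed.
#' @export
setClass("ClassifierModel",
  representation(arch = "character", params = "list", inputSpec = "list",
                 trainingLog = "data.frame", seed = "integer")
)

setValidity("ClassifierModel", function(object) {
  if (!object@arch %in% c("logreg", "cnn", "rnn")) return("unknown arch")
  TRUE
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel: %s (C = %d, lags: %s)\n", object@arch,
              object@inputSpec$C,
              if (length(object@inputSpec$stackLags))
                paste(object@inputSpec$stackLags, collapse = ",")
              else "none"))
  if (nrow(object@trainingLog))
    cat(sprintf("  %d epochs; final train loss %.4f\n",
                nrow(object@trainingLog),
                object@trainingLog$trainLoss[nrow(object@trainingLog)]))
})

# Pool sessions into one big frame/label matrix, stacking if requested.
poolSessions <- function(sessions, lags = NULL) {
  Xs <- list(); ys <- list()
  for (s in sessions) {
    fr <- s$frames
    if (!is.null(lags)) fr <- stackContext(fr, lags)
    if (nFrames(fr) != nFrames(s$labels))
      stop("frames and labels disagree in length")
    Xs[[length(Xs) + 1]] <- fr@values
    ys[[length(ys) + 1]] <- s$labels@labels
  }
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

checkTrainInputs <- function(train, val, cfg) {
  for (s in c(train, val)) {
    stopifnot(is(s$frames, "FrameSequence"), is(s$labels, "LabelSequence"))
    checkBinaryLabels(s$labels@labels, "training labels")
    if (length(s$frames@stackLags))
      stop("pass unstacked frames; stacking is applied internally per arch")
  }
  y <- unlist(lapply(train, function(s) s$labels@labels))
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  if (cfg$selectBestByVal && length(val) == 0)
    stop("selectBestByVal requires validation data")
  invisible(TRUE)
}

#' Train a frame-wise speech/non-speech classifier
#'
#' @param train list of sessions, each a list with elements \code{frames}
#'   (unstacked, z-scored \linkS4class{FrameSequence}) and \code{labels}
#'   (binary \linkS4class{LabelSequence} — TICC-estimated or reference).
#' @param val validation sessions in the same format (required when
#'   \code{selectBestByVal}).
#' @param cfg a \code{\link{trainingConfig}}.
#' @return A \linkS4class{ClassifierModel}.
#' @export
trainClassifier <- function(train, val = list(), cfg = trainingConfig()) {
  stopifnot(inherits(cfg, "trainingConfig"))
  if (length(train) && !is.null(train$frames)) train <- list(train)
  if (length(val) && !is.null(val$frames)) val <- list(val)
  checkTrainInputs(train, val, cfg)
  C <- ncol(train[[1]]$frames@values)
  set.seed(cfg$seed)
  switch(cfg$arch,
         logreg = trainLogreg(train, val, cfg, C),
         cnn = trainCnn(train, val, cfg, C),
         rnn = trainRnn(train, val, cfg, C))
}

## ---- logistic regression ---------------------------------------------------

trainLogreg <- function(train, val, cfg, C) {
  d <- poolSessions(train, cfg$stackLagsFrames)
  n <- nrow(d$X)
  wts <- rep(1, n)
  if (cfg$classWeighting) {
    tab <- table(d$y)
    wts <- as.numeric(n / (2 * tab[as.character(d$y)]))
  }
  fit <- glmnet::glmnet(d$X, factor(d$y, levels = c(0, 1)),
                        family = "binomial", alpha = 1,
                        lambda = 1 / (cfg$l1Strength * n), weights = wts,
                        standardize = FALSE)
  beta <- as.numeric(fit$beta[, 1])
  b0 <- as.numeric(fit$a0[1])
  trainLoss <- {
    eta <- drop(d$X %*% beta) + b0
    -mean(d$y * eta - log1p(exp(eta)))
  }
  new("ClassifierModel", arch = "logreg",
      params = list(beta = beta, b0 = b0),
      inputSpec = list(C = C, stackLags = cfg$stackLagsFrames),
      trainingLog = data.frame(epoch = 1L, trainLoss = trainLoss,
                               valLoss = NA_real_),
      seed = cfg$seed)
}

## ---- CNN -------------------------------------------------------------------

trainCnn <- function(train, val, cfg, C) {
  L <- length(cfg$stackLagsFrames)
  d <- poolSessions(train, cfg$stackLagsFrames)
  n <- nrow(d$X)
  params <- cnnInit(C, L, nOut = cfg$nOut)
  geom <- attr(params, "geom")
  opt <- adamInit(params)
  dv <- if (length(val)) poolSessions(val, cfg$stackLagsFrames) else NULL
  log <- data.frame()
  best <- NULL; bestVal <- Inf
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c(); sizes <- c()
    for (start in seq(1, n, by = cfg$batchSize)) {
      idx <- ord[start:min(start + cfg$batchSize - 1, n)]
      B <- length(idx)
      fw <- cnnForward(params, d$X[idx, , drop = FALSE], B)
      ce <- softmaxCE(fw$logits, pmin(d$y[idx] + 1L, cfg$nOut))
      gr <- cnnBackward(params, fw, ce$dZ, B)
      upd <- adamStep(params, gr, opt, cfg$learningRate)
      attr(upd$params, "geom") <- geom
      params <- upd$params; opt <- upd$state
      losses <- c(losses, ce$loss); sizes <- c(sizes, B)
    }
    trainLoss <- sum(losses * sizes) / sum(sizes)
    valLoss <- NA_real_
    if (!is.null(dv)) {
      fwv <- cnnForward(params, dv$X, nrow(dv$X))
      valLoss <- softmaxCE(fwv$logits, pmin(dv$y + 1L, cfg$nOut))$loss
      if (cfg$selectBestByVal && valLoss < bestVal) {
        bestVal <- valLoss; best <- params
      }
    }
    log <- rbind(log, data.frame(epoch = ep, trainLoss = trainLoss,
                                 valLoss = valLoss))
  }
  if (cfg$selectBestByVal && !is.null(best)) params <- best
  new("ClassifierModel", arch = "cnn", params = list(net = params),
      inputSpec = list(C = C, stackLags = cfg$stackLagsFrames),
      trainingLog = log, seed = cfg$seed)
}

## ---- RNN (2 x LSTM-100 + linear head) --------------------------------------

rnnInitParams <- function(C, H, nOut) {
  list(l1 = lstmInitLayer(C, H), l2 = lstmInitLayer(H, H),
       Wy = matrix(0, H, nOut), by = numeric(nOut))
}

rnnFlatten <- function(p) {
  list(Wx1 = p$l1$Wx, Wh1 = p$l1$Wh, b1 = p$l1$b,
       Wx2 = p$l2$Wx, Wh2 = p$l2$Wh, b2 = p$l2$b,
       Wy = p$Wy, by = p$by)
}

rnnUnflatten <- function(f) {
  list(l1 = list(Wx = f$Wx1, Wh = f$Wh1, b = f$b1),
       l2 = list(Wx = f$Wx2, Wh = f$Wh2, b = f$b2),
       Wy = f$Wy, by = f$by)
}

rnnSessionLoss <- function(p, X, y, H, nOut) {
  h1 <- matrix(0, 1, H); c1 <- h1; h2 <- h1; c2 <- h1
  total <- 0
  k <- 500L
  for (start in seq(1, nrow(X), by = k)) {
    idx <- start:min(start + k - 1, nrow(X))
    f1 <- lstmChunkForward(X[idx, , drop = FALSE], h1, c1, p$l1)
    f2 <- lstmChunkForward(f1$H, h2, c2, p$l2)
    logits <- sweep(f2$H %*% p$Wy, 2, p$by, "+")
    total <- total + softmaxCE(logits, pmin(y[idx] + 1L, nOut))$loss *
      length(idx)
    h1 <- f1$h; c1 <- f1$c; h2 <- f2$h; c2 <- f2$c
  }
  total / nrow(X)
}

trainRnn <- function(train, val, cfg, C) {
  H <- cfg$hiddenSize
  p <- rnnInitParams(C, H, cfg$nOut)
  flat <- rnnFlatten(p)
  opt <- adamInit(flat)
  log <- data.frame()
  best <- flat; bestVal <- Inf
  k <- cfg$tbpttK1
  for (ep in seq_len(cfg$epochs)) {
    ordSess <- sample.int(length(train))
    losses <- c(); sizes <- c()
    for (si in ordSess) {
      X <- train[[si]]$frames@values
      y <- train[[si]]$labels@labels
      h1 <- matrix(0, 1, H); c1 <- h1; h2 <- h1; c2 <- h1
      for (start in seq(1, nrow(X), by = k)) {
        idx <- start:min(start + k - 1, nrow(X))
        p <- rnnUnflatten(flat)
        f1 <- lstmChunkForward(X[idx, , drop = FALSE], h1, c1, p$l1)
        f2 <- lstmChunkForward(f1$H, h2, c2, p$l2)
        logits <- sweep(f2$H %*% p$Wy, 2, p$by, "+")
        ce <- softmaxCE(logits, pmin(y[idx] + 1L, cfg$nOut))
        dH2top <- ce$dZ %*% t(p$Wy)
        b2 <- lstmChunkBackward(f2, dH2top, p$l2)
        b1 <- lstmChunkBackward(f1, b2$dX, p$l1)
        gr <- list(Wx1 = b1$dWx, Wh1 = b1$dWh, b1 = b1$db,
                   Wx2 = b2$dWx, Wh2 = b2$dWh, b2 = b2$db,
                   Wy = crossprod(f2$H, ce$dZ), by = colSums(ce$dZ))
        upd <- adamStep(flat, gr, opt, cfg$learningRate)
        flat <- upd$params; opt <- upd$state
        # carry state (detached) across chunk boundaries
        h1 <- f1$h; c1 <- f1$c; h2 <- f2$h; c2 <- f2$c
        losses <- c(losses, ce$loss); sizes <- c(sizes, length(idx))
      }
    }
    trainLoss <- sum(losses * sizes) / sum(sizes)
    valLoss <- NA_real_
    if (length(val)) {
      pv <- rnnUnflatten(flat)
      vl <- vapply(val, function(s)
        rnnSessionLoss(pv, s$frames@values, s$labels@labels, H, cfg$nOut),
        numeric(1))
      vn <- vapply(val, function(s) nrow(s$frames@values), numeric(1))
      valLoss <- sum(vl * vn) / sum(vn)
      if (cfg$selectBestByVal && valLoss < bestVal) {
        bestVal <- valLoss; best <- flat
      }
    }
    log <- rbind(log, data.frame(epoch = ep, trainLoss = trainLoss,
                                 valLoss = valLoss))
  }
  if (cfg$selectBestByVal) flat <- best
  new("ClassifierModel", arch = "rnn",
      params = c(rnnUnflatten(flat), list(H = H, nOut = cfg$nOut)),
      inputSpec = list(C = C, stackLags = integer()),
      trainingLog = log, seed = cfg$seed)
}

## ---- prediction ------------------------------------------------------------

#' Fresh streaming state for a classifier
#'
#' For the stacked architectures (logreg, cnn) the state is a zero-filled
#' ring buffer of past frames matching the offline zero-padding convention;
#' for the RNN it is the hidden/cell state of both LSTM layers.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @return opaque state for \code{\link{predictStep}}.
#' @export
freshState <- function(model) {
  stopifnot(is(model, "ClassifierModel"))
  C <- model@inputSpec$C
  if (model@arch == "rnn") {
    H <- model@params$H
    z <- matrix(0, 1, H)
    list(arch = "rnn", h1 = z, c1 = z, h2 = z, c2 = z)
  } else {
    maxLag <- max(model@inputSpec$stackLags)
    list(arch = model@arch, hist = matrix(0, maxLag + 1L, C))
  }
}

# Single stacked-frame forward pass shared by offline and streaming paths.
predictFrameStacked <- function(model, stacked) {
  if (model@arch == "logreg") {
    eta <- sum(stacked * model@params$beta) + model@params$b0
    as.integer(eta > 0)
  } else {
    fw <- cnnForward(model@params$net, matrix(stacked, 1), 1L)
    # class decision over the two VAD units (extra configured output units
    # receive no targets during training and take no part in the decision)
    as.integer(which.max(fw$logits[1, 1:2]) - 1L)
  }
}

#' Single-frame streaming prediction
#'
#' Folding \code{predictStep} over a sequence reproduces
#' \code{\link{predictOffline}} exactly, frame by frame, for all three
#' architectures; both run the identical single-frame forward pass.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param frame numeric vector of C (unstacked) features.
#' @param state state from the previous call or \code{\link{freshState}}.
#' @return list with \code{class} (0/1) and updated \code{state}.
#' @export
predictStep <- function(model, frame, state = freshState(model)) {
  stopifnot(is(model, "ClassifierModel"))
  if (!identical(state$arch, model@arch))
    stop("state does not belong to this model architecture")
  if (length(frame) != model@inputSpec$C)
    stop("frame dimension does not match the model input spec")
  if (model@arch == "rnn") {
    p <- model@params
    s1 <- lstmCell(matrix(frame, 1), state$h1, state$c1,
                   p$l1$Wx, p$l1$Wh, p$l1$b)
    s2 <- lstmCell(s1$h, state$h2, state$c2, p$l2$Wx, p$l2$Wh, p$l2$b)
    logits <- s2$h %*% p$Wy + rep(p$by, each = 1L)
    cls <- as.integer(which.max(logits[1, 1:2]) - 1L)
    list(class = cls,
         state = list(arch = "rnn", h1 = s1$h, c1 = s1$c,
                      h2 = s2$h, c2 = s2$c))
  } else {
    hist <- rbind(matrix(frame, 1), state$hist[-nrow(state$hist), ,
                                               drop = FALSE])
    stacked <- as.vector(t(hist[model@inputSpec$stackLags + 1L, ,
                                drop = FALSE]))
    cls <- predictFrameStacked(model, stacked)
    list(class = cls, state = list(arch = model@arch, hist = hist))
  }
}

#' Offline frame-wise prediction
#'
#' Runs the classifier over a whole session. Implemented as a fold of the
#' same single-frame forward pass used in streaming, so the offline and
#' streaming class sequences are identical by construction. Context
#' stacking (logreg/cnn) is applied internally; the RNN carries its
#' recurrent state across the sequence.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param frames an unstacked \linkS4class{FrameSequence}.
#' @return binary \linkS4class{LabelSequence}.
#' @export
predictOffline <- function(model, frames) {
  stopifnot(is(model, "ClassifierModel"), is(frames, "FrameSequence"))
  if (!frames@normalized)
    warning("frames are not flagged as z-scored; predictions assume ",
            "normalized input")
  if (length(frames@stackLags))
    stop("pass unstacked frames; stacking is applied internally")
  if (ncol(frames@values) != model@inputSpec$C)
    stop("frame dimension does not match the model input spec")
  T <- nrow(frames@values)
  out <- integer(T)
  st <- freshState(model)
  for (t in seq_len(T)) {
    r <- predictStep(model, frames@values[t, ], st)
    out[t] <- r$class
    st <- r$state
  }
  LabelSequence(out, frameShift = frames@frameShift,
                startTime = frames@startTime)
}
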