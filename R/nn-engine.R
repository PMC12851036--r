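## Minimal feed-forward / back-propagation engine in base R.
##
## The heavy lifting of every 1-D convolution is a single GEMM on an
## im2col-unrolled input (unrolling/scatter in compiled code); all other
## layers are vectorized array arithmetic. Signal arrays are stored
## [channels, time, batch]; dense activations [features, batch]. Only
## what the two pinned architectures need is implemented: bias-free
## conv1d (length-preserving, odd kernels), kernel-3 stride-1 max
## pooling, affine batch normalization over channels, ReLU, global
## average pooling, dense layers with bias, inverted dropout, softmax
## cross-entropy, mean-squared / euclidean-distance losses and Adam.

## ---- primitive layers ------------------------------------------------------

.convForward <- function(X, W, k) {
  d <- dim(X)
  Xcol <- .im2col1d(X, d[1L], d[2L], d[3L], as.integer(k))
  Y <- W %*% Xcol
  list(Y = array(Y, c(nrow(W), d[2L], d[3L])), Xcol = Xcol, dimX = d, k = k)
}

.convBackward <- function(cache, W, dY) {
  dY2 <- matrix(dY, nrow(W))
  dW <- tcrossprod(dY2, cache$Xcol)
  dXcol <- crossprod(W, dY2)
  dX <- .col2im1d(dXcol, cache$dimX[1L], cache$dimX[2L], cache$dimX[3L],
                  as.integer(cache$k))
  list(dW = dW, dX = dX)
}

.maxpool3Forward <- function(X) {
  d <- dim(X)
  mp <- .maxpool3C(X, d[1L], d[2L], d[3L])
  list(Y = mp$y, argmax = mp$argmax, dimX = d)
}

.maxpool3Backward <- function(cache, dY) {
  d <- cache$dimX
  .maxpool3BackwardC(dY, cache$argmax, d[1L], d[2L], d[3L])
}

## Batch normalization over channels (rows); X is [C, N] with
## N = time x batch. Row-wise recycling relies on column-major layout.
.bnForward <- function(X, gamma, beta, state, training, momentum = 0.1,
                       eps = 1e-5) {
  if (training) {
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)
    if (isTRUE(state$fresh)) {  # seed running stats from the first batch
      state$mean <- mu
      state$var <- v
      state$fresh <- FALSE
    } else {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * v
    }
  } else {
    mu <- state$mean
    v <- state$var
    xc <- X - mu
  }
  isd <- 1 / sqrt(v + eps)
  xhat <- xc * isd
  list(Y = gamma * xhat + beta, xhat = xhat, isd = isd, state = state)
}

.bnBackward <- function(cache, gamma, dY) {
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  dX <- cache$isd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.gapForward <- function(X) {
  d <- dim(X)
  Y <- colMeans(aperm(X, c(2L, 1L, 3L)))  # [C, B]
  list(Y = matrix(Y, d[1L], d[3L]), dimX = d)
}

.gapBackward <- function(cache, dY) {
  d <- cache$dimX
  aperm(array(dY / d[2L], c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
}

## ---- Adam ------------------------------------------------------------------

.adamInit <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1c <- 1 - beta1^state$t
  b2c <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1c) / (sqrt(state$v[[nm]] / b2c) + eps)
  }
  list(params = params, state = state)
}

.lrAt <- function(cfg, epoch) {
  if (cfg@lrSchedule == "cosine" && cfg@epochs > 1)
    cfg@learningRate * 0.5 * (1 + cos(pi * (epoch - 1) / (cfg@epochs - 1)))
  else cfg@learningRate
}

## ---- losses ----------------------------------------------------------------

.softmaxCE <- function(logits, yIdx) {
  B <- ncol(logits)
  mx <- apply(logits, 2L, max)
  ez <- exp(sweep(logits, 2L, mx))
  p <- sweep(ez, 2L, colSums(ez), "/")
  picked <- p[cbind(yIdx, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(yIdx, seq_len(B))] <- dlogits[cbind(yIdx, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B, probs = p)
}

## ---- inception-style classifier -------------------------------------------

.heInit <- function(nOut, fanIn) {
  matrix(stats::rnorm(nOut * fanIn, 0, sqrt(2 / fanIn)), nOut, fanIn)
}

## Trainable parameters of the classifier, exact to the pinned layout:
## per block a kernel-1 bottleneck (bias-free), three parallel branch
## convolutions, a kernel-1 convolution after the max-pool branch, and
## an affine normalization over the 4*nFilters concatenated channels;
## then a dense head with bias. Uses the current RNG stream.
.inceptionInitParams <- function(spec) {
  nf <- spec@nFilters
  ks <- spec@kernelSizes
  conc <- 4L * nf
  params <- list()
  cin <- spec@inChannels
  for (b in seq_len(spec@depth)) {
    pf <- sprintf("b%d", b)
    params[[paste0(pf, ".bottleneck.W")]] <- .heInit(nf, cin)
    for (j in 1:3)
      params[[sprintf("%s.branch%d.W", pf, j)]] <- .heInit(nf, nf * ks[j])
    params[[paste0(pf, ".mp.W")]] <- .heInit(nf, cin)
    params[[paste0(pf, ".bn.gamma")]] <- rep(1, conc)
    params[[paste0(pf, ".bn.beta")]] <- rep(0, conc)
    cin <- conc
  }
  params[["head.W"]] <- .heInit(spec@nClasses, conc) / sqrt(2)
  params[["head.b"]] <- rep(0, spec@nClasses)
  params
}

.inceptionInitBnState <- function(spec) {
  conc <- 4L * spec@nFilters
  lapply(seq_len(spec@depth), function(b)
    list(mean = rep(0, conc), var = rep(1, conc), fresh = TRUE))
}

.incBlockForward <- function(X, params, spec, b, bnState, training) {
  pf <- sprintf("b%d", b)
  nf <- spec@nFilters
  ks <- spec@kernelSizes
  cb <- .convForward(X, params[[paste0(pf, ".bottleneck.W")]], 1L)
  br <- lapply(1:3, function(j)
    .convForward(cb$Y, params[[sprintf("%s.branch%d.W", pf, j)]], ks[j]))
  mp <- .maxpool3Forward(X)
  mpc <- .convForward(mp$Y, params[[paste0(pf, ".mp.W")]], 1L)
  d <- dim(X)
  Z <- array(0, c(4L * nf, d[2L], d[3L]))
  for (j in 1:3) Z[((j - 1L) * nf + 1L):(j * nf), , ] <- br[[j]]$Y
  Z[(3L * nf + 1L):(4L * nf), , ] <- mpc$Y
  Z2 <- matrix(Z, 4L * nf)
  bn <- .bnForward(Z2, params[[paste0(pf, ".bn.gamma")]],
                   params[[paste0(pf, ".bn.beta")]], bnState, training)
  A2 <- bn$Y
  A2[A2 < 0] <- 0
  list(Y = array(A2, c(4L * nf, d[2L], d[3L])), cb = cb, br = br, mp = mp,
       mpc = mpc, bn = bn, preRelu = bn$Y, state = bn$state)
}

.incBlockBackward <- function(cache, params, spec, b, dY) {
  pf <- sprintf("b%d", b)
  nf <- spec@nFilters
  dA2 <- matrix(dY, 4L * nf)
  dA2[cache$preRelu <= 0] <- 0
  bnb <- .bnBackward(cache$bn, params[[paste0(pf, ".bn.gamma")]], dA2)
  dZ <- array(bnb$dX, dim(cache$Y))
  grads <- list()
  grads[[paste0(pf, ".bn.gamma")]] <- bnb$dgamma
  grads[[paste0(pf, ".bn.beta")]] <- bnb$dbeta
  dY0 <- NULL
  for (j in 1:3) {
    cj <- .convBackward(cache$br[[j]],
                        params[[sprintf("%s.branch%d.W", pf, j)]],
                        dZ[((j - 1L) * nf + 1L):(j * nf), , , drop = FALSE])
    grads[[sprintf("%s.branch%d.W", pf, j)]] <- cj$dW
    dY0 <- if (is.null(dY0)) cj$dX else dY0 + cj$dX
  }
  cbB <- .convBackward(cache$cb, params[[paste0(pf, ".bottleneck.W")]], dY0)
  grads[[paste0(pf, ".bottleneck.W")]] <- cbB$dW
  mpcB <- .convBackward(cache$mpc, params[[paste0(pf, ".mp.W")]],
                        dZ[(3L * nf + 1L):(4L * nf), , , drop = FALSE])
  grads[[paste0(pf, ".mp.W")]] <- mpcB$dW
  dXmp <- .maxpool3Backward(cache$mp, mpcB$dX)
  list(dX = cbB$dX + dXmp, grads = grads)
}

.inceptionForward <- function(X, params, spec, bnStates, training = FALSE) {
  caches <- vector("list", spec@depth)
  A <- X
  for (b in seq_len(spec@depth)) {
    caches[[b]] <- .incBlockForward(A, params, spec, b, bnStates[[b]],
                                    training)
    bnStates[[b]] <- caches[[b]]$state
    A <- caches[[b]]$Y
  }
  gp <- .gapForward(A)
  logits <- params[["head.W"]] %*% gp$Y + params[["head.b"]]
  list(logits = logits, caches = caches, gap = gp, bnStates = bnStates)
}

.inceptionBackward <- function(fw, params, spec, dlogits) {
  grads <- list()
  grads[["head.W"]] <- tcrossprod(dlogits, fw$gap$Y)
  grads[["head.b"]] <- rowSums(dlogits)
  dGap <- crossprod(params[["head.W"]], dlogits)
  dA <- .gapBackward(fw$gap, dGap)
  for (b in rev(seq_len(spec@depth))) {
    bb <- .incBlockBackward(fw$caches[[b]], params, spec, b, dA)
    grads <- c(grads, bb$grads)
    dA <- bb$dX
  }
  grads
}

## ---- multilayer perceptron -------------------------------------------------

## Dense ladder with bias everywhere, ReLU between layers, inverted
## dropout after each hidden activation. Uses the current RNG stream.
.mlpInitParams <- function(spec) {
  sizes <- c(spec@inputDim, spec@hidden, spec@outputDim)
  params <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    params[[sprintf("W%d", i)]] <- .heInit(sizes[i + 1L], sizes[i])
    params[[sprintf("b%d", i)]] <- rep(0, sizes[i + 1L])
  }
  params
}

.mlpForward <- function(X, params, spec, training = FALSE) {
  nl <- length(spec@hidden) + 1L
  acts <- list(X)
  masks <- vector("list", nl)
  A <- X
  for (i in seq_len(nl)) {
    Z <- params[[sprintf("W%d", i)]] %*% A + params[[sprintf("b%d", i)]]
    if (i < nl) {
      Z[Z < 0] <- 0
      if (training && spec@dropout > 0) {
        mk <- (matrix(stats::runif(length(Z)), nrow(Z)) >= spec@dropout) /
          (1 - spec@dropout)
        Z <- Z * mk
        masks[[i]] <- mk
      }
    }
    acts[[i + 1L]] <- Z
    A <- Z
  }
  list(out = A, acts = acts, masks = masks)
}

.mlpBackward <- function(fw, params, spec, dOut) {
  nl <- length(spec@hidden) + 1L
  grads <- list()
  dA <- dOut
  for (i in rev(seq_len(nl))) {
    if (i < nl) {
      if (!is.null(fw$masks[[i]])) dA <- dA * fw$masks[[i]]
      dA[fw$acts[[i + 1L]] <= 0] <- 0
    }
    grads[[sprintf("W%d", i)]] <- tcrossprod(dA, fw$acts[[i]])
    grads[[sprintf("b%d", i)]] <- rowSums(dA)
    if (i > 1L) dA <- crossprod(params[[sprintf("W%d", i)]], dA)
  }
  grads
}
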