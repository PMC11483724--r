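## Internal CNN engine: batched im2col convolution (BLAS GEMM), ReLU,
## 2x2 max pooling, dropout, linear regression head, Adam with L2 on
## weights.
##
## Activations are numeric arrays laid out (height, width, batch, channel):
## with the batch dimension BEFORE the channel dimension, the im2col matrix
## (rows ordered pixel-fastest then image, columns ordered kernel offset
## then input channel) and its inverse are plain reshapes of contiguous
## memory, so no transpositions of large arrays are ever needed.

im2col <- function(X, k) {
  d <- dim(X); H <- d[1L]; W <- d[2L]; B <- d[3L]; C <- d[4L]
  p <- (k - 1L) %/% 2L
  Xp <- array(0, c(H + 2L * p, W + 2L * p, B, C))
  Xp[p + seq_len(H), p + seq_len(W), , ] <- X
  M <- matrix(0, H * W * B, k * k * C)
  col <- 0L
  ri <- seq_len(H); ci <- seq_len(W)
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    sub <- Xp[di + ri, dj + ci, , , drop = FALSE]
    dim(sub) <- c(H * W * B, C)
    M[, col + seq_len(C)] <- sub
    col <- col + C
  }
  M
}

## Gradient of a same-padded convolution w.r.t. its input, computed as a
## transposed convolution: im2col of the output gradient times the
## offset-reversed, in/out-swapped kernel. Pure reshapes + one GEMM; no
## scatter-add.
convBackwardInput <- function(dZarr, W, k, Cin) {
  d <- dim(dZarr) # (H, W, B, Cout)
  Cout <- d[4L]
  nOff <- k * k
  Wb <- matrix(0, nOff * Cout, Cin)
  for (o in seq_len(nOff)) {
    rows <- (o - 1L) * Cin + seq_len(Cin)
    rowsRev <- (nOff - o) * Cout + seq_len(Cout)
    Wb[rowsRev, ] <- t(W[rows, , drop = FALSE])
  }
  dX <- im2col(dZarr, k) %*% Wb
  dim(dX) <- c(d[1L], d[2L], d[3L], Cin)
  dX
}

maxpoolForward <- function(X) {
  d <- dim(X)
  Ho <- d[1L] %/% 2L; Wo <- d[2L] %/% 2L
  i1 <- seq_len(Ho) * 2L - 1L; j1 <- seq_len(Wo) * 2L - 1L
  a <- X[i1, j1, , , drop = FALSE]; b <- X[i1 + 1L, j1, , , drop = FALSE]
  cc <- X[i1, j1 + 1L, , , drop = FALSE]
  dd <- X[i1 + 1L, j1 + 1L, , , drop = FALSE]
  Y <- pmax(a, b, cc, dd)
  ## deterministic first-match argmax in the fixed order a, b, cc, dd
  g1 <- a == Y
  g2 <- (b == Y) & !g1
  g3 <- (cc == Y) & !(g1 | g2)
  g4 <- (dd == Y) & !(g1 | g2 | g3)
  list(Y = Y, g = list(g1, g2, g3, g4), dimIn = d)
}

maxpoolBackward <- function(dY, cache) {
  d <- cache$dimIn
  Ho <- d[1L] %/% 2L; Wo <- d[2L] %/% 2L
  i1 <- seq_len(Ho) * 2L - 1L; j1 <- seq_len(Wo) * 2L - 1L
  dX <- array(0, d)
  dX[i1, j1, , ] <- dY * cache$g[[1L]]
  dX[i1 + 1L, j1, , ] <- dY * cache$g[[2L]]
  dX[i1, j1 + 1L, , ] <- dY * cache$g[[3L]]
  dX[i1 + 1L, j1 + 1L, , ] <- dY * cache$g[[4L]]
  dX
}

## Spatial dimensions entering each conv layer and the flattened feature
## count, for a given architecture.
archDims <- function(arch) {
  h <- arch@inputShape[1L]; w <- arch@inputShape[2L]
  cin <- arch@inputShape[3L]
  dims <- vector("list", 3L)
  for (l in 1:3) {
    dims[[l]] <- c(h = h, w = w, cin = cin)
    cin <- arch@convChannels[l]
    if (l %in% arch@poolAfter) { h <- h %/% 2L; w <- w %/% 2L }
  }
  list(layers = dims, outH = h, outW = w,
       nFeat = h * w * arch@convChannels[3L])
}

## Flatten (h, w, B, C) conv output into per-image feature columns
## (nFeat x B); feature order (h, w, c) column-major, as the dense head
## expects. The single small transposition of the whole engine.
flattenFeatures <- function(A) {
  d <- dim(A)
  Fmat <- aperm(A, c(1L, 2L, 4L, 3L))
  dim(Fmat) <- c(d[1L] * d[2L] * d[4L], d[3L])
  Fmat
}

unflattenFeatures <- function(Fmat, d) {
  dim(Fmat) <- c(d[1L], d[2L], d[4L], d[3L])
  aperm(Fmat, c(1L, 2L, 4L, 3L))
}

## Forward pass. dropMask: NULL for inference, otherwise (nFeat x B)
## inverted-dropout mask. Returns predictions and (optionally) all caches.
cnnForward <- function(params, arch, X, dropMask = NULL, keepCache = FALSE,
                       M1 = NULL) {
  k <- arch@kernelSize
  B <- dim(X)[3L]
  caches <- if (keepCache) vector("list", 3L)
  A <- X
  for (l in 1:3) {
    d <- dim(A)
    M <- if (l == 1L && !is.null(M1)) M1 else im2col(A, k)
    Zmat <- M %*% params[[paste0("W", l)]]
    Zmat <- Zmat + rep(params[[paste0("b", l)]], each = nrow(Zmat))
    relu <- Zmat > 0
    Amat <- Zmat * relu
    dim(Amat) <- c(d[1L], d[2L], B, arch@convChannels[l])
    pc <- NULL
    if (l %in% arch@poolAfter) {
      pc <- maxpoolForward(Amat)
      Amat <- pc$Y
    }
    if (keepCache)
      caches[[l]] <- list(M = M, relu = relu, dimIn = d, pool = pc)
    A <- Amat
  }
  Fmat <- flattenFeatures(A)
  if (!is.null(dropMask)) Fmat <- Fmat * dropMask
  pred <- as.numeric(crossprod(Fmat, params$Wd) + params$bd)
  if (!keepCache) return(list(pred = pred))
  list(pred = pred, caches = caches, Fmat = Fmat, featDim = dim(A))
}

## Backward pass for the half mean squared error; returns gradient list.
cnnBackward <- function(params, arch, fwd, targets, dropMask = NULL) {
  B <- length(fwd$pred)
  dpred <- (fwd$pred - targets) / B
  grads <- list()
  grads$Wd <- fwd$Fmat %*% dpred
  grads$bd <- sum(dpred)
  dF <- params$Wd %*% t(dpred)          # nFeat x B
  if (!is.null(dropMask)) dF <- dF * dropMask
  dA <- unflattenFeatures(dF, fwd$featDim)
  k <- arch@kernelSize
  for (l in 3:1) {
    cache <- fwd$caches[[l]]
    if (!is.null(cache$pool)) dA <- maxpoolBackward(dA, cache$pool)
    dZmat <- dA
    dim(dZmat) <- dim(cache$relu)
    dZmat <- dZmat * cache$relu
    grads[[paste0("W", l)]] <- crossprod(cache$M, dZmat)
    grads[[paste0("b", l)]] <- colSums(dZmat)
    if (l > 1L) {
      d <- cache$dimIn
      dZarr <- dZmat
      dim(dZarr) <- c(d[1L], d[2L], d[3L], arch@convChannels[l])
      dA <- convBackwardInput(dZarr, params[[paste0("W", l)]], k, d[4L])
    }
  }
  grads
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, lambda,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  weightNames <- c("W1", "W2", "W3", "Wd")
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (lambda > 0 && nm %in% weightNames) g <- g + lambda * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Stack standardized slices into a (H, W, N, 3) batch tensor
## (batch-before-channel layout used throughout the engine).
slicesToArray <- function(sliceList, inputShape = c(49L, 56L, 3L)) {
  N <- length(sliceList)
  X <- array(0, c(inputShape[1:2], N, inputShape[3L]))
  for (i in seq_len(N)) {
    ch <- sliceList[[i]]@channels
    if (!identical(dim(ch), as.integer(inputShape)))
      stop(sprintf("slice %d has shape %s, expected %s", i,
                   paste(dim(ch), collapse = "x"),
                   paste(inputShape, collapse = "x")))
    X[, , i, ] <- ch
  }
  X
}
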