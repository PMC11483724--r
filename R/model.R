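## User-facing model operations: construction, loss, training, prediction,
## and the hyperparameter grid search.

#' Build the 3-layer CNN regressor
#'
#' Initializes a [ThrombusNet-class] for the configured architecture:
#' three same-padded convolutional layers (rectifier activations, 2x2 max
#' pooling after the layers listed in `poolAfter`), flattening, dropout
#' (rate supplied at training time) and a single linear regression output.
#' Kernels use He-normal initialization scaled by fan-in; biases start at
#' zero. The same seed always yields identical initial parameters.
#'
#' @param arch an [ArchConfig-class].
#' @param seed integer seed driving the initialization.
#' @return An untrained [ThrombusNet-class].
#' @export
buildNetwork <- function(arch = ArchConfig(), seed = 1L) {
  validObject(arch)
  k <- arch@kernelSize
  dims <- archDims(arch)
  params <- withSeed(seed, {
    p <- list()
    for (l in 1:3) {
      fanIn <- k * k * dims$layers[[l]][["cin"]]
      cout <- arch@convChannels[l]
      p[[paste0("W", l)]] <- matrix(rnorm(fanIn * cout, 0, sqrt(2 / fanIn)),
                                    fanIn, cout)
      p[[paste0("b", l)]] <- numeric(cout)
    }
    p$Wd <- matrix(rnorm(dims$nFeat, 0, sqrt(2 / dims$nFeat)), dims$nFeat, 1L)
    p$bd <- 0
    p
  })
  new("ThrombusNet", arch = arch, params = params)
}

#' Number of trainable parameters
#'
#' @param net a [ThrombusNet-class].
#' @return integer parameter count.
#' @export
nParameters <- function(net) {
  sum(vapply(net@params, length, 0L))
}

#' Half mean squared error
#'
#' `mean((predictions - targets)^2) / 2`, the training loss of the
#' regression network.
#'
#' @param predictions,targets equal-length numeric vectors.
#' @return nonnegative scalar.
#' @export
halfMseLoss <- function(predictions, targets) {
  if (length(predictions) != length(targets) || !length(predictions))
    stop("halfMseLoss: predictions and targets must have equal length >= 1")
  mean((predictions - targets)^2) / 2
}

#' Train the CNN with mini-batch Adam
#'
#' Runs `nEpochs` passes of shuffled mini-batch Adam on the half mean
#' squared error with L2 penalty `l2Lambda` on the weights (not biases) and
#' inverted dropout before the regression head. The RNG stream (shuffling
#' and dropout) is scoped under `hp@seed`, so a fixed seed reproduces the
#' loss history exactly. With `nEpochs = 0` the input network is returned
#' unchanged with an empty history.
#'
#' @param net a [ThrombusNet-class].
#' @param sliceList list of canvas-standardized [SliceImage-class].
#' @param targets per-slice RBC percentages in \[0, 100\] (every slice of a
#'   thrombus carries the thrombus's histological value).
#' @param hp a [HyperParams-class].
#' @return The trained [ThrombusNet-class]; per-epoch mean training loss in
#'   `@lossHistory`.
#' @export
trainNetwork <- function(net, sliceList, targets, hp) {
  validObject(hp)
  N <- length(sliceList)
  if (N < 1L) stop("trainNetwork: empty training set")
  if (length(targets) != N)
    stop("trainNetwork: need one target per slice")
  if (any(targets < 0 | targets > 100))
    stop("trainNetwork: targets must be RBC percentages in [0, 100]")
  if (hp@nEpochs == 0L) { net@lossHistory <- numeric(); return(net) }
  arch <- net@arch
  X <- slicesToArray(sliceList, arch@inputShape)
  nFeat <- archDims(arch)$nFeat
  params <- net@params
  history <- numeric(hp@nEpochs)
  keep <- 1 - hp@dropoutRate
  ## the layer-1 im2col of the (static) training set is reused across all
  ## epochs when it fits comfortably in memory
  HW <- prod(arch@inputShape[1:2])
  m1Bytes <- 8 * HW * N * arch@kernelSize^2 * arch@inputShape[3L]
  M1all <- if (m1Bytes < 1.5e9) im2col(X, arch@kernelSize)
  withSeed(hp@seed, {
    state <- adamInit(params)
    for (epoch in seq_len(hp@nEpochs)) {
      perm <- sample.int(N)
      losses <- numeric()
      for (start in seq(1L, N, by = hp@batchSize)) {
        idx <- perm[start:min(start + hp@batchSize - 1L, N)]
        Xb <- X[, , idx, , drop = FALSE]
        yb <- targets[idx]
        M1b <- if (!is.null(M1all))
          M1all[as.integer(outer(seq_len(HW), (idx - 1L) * HW, `+`)), ,
                drop = FALSE]
        dropMask <- NULL
        if (hp@dropoutRate > 0)
          dropMask <- matrix((runif(nFeat * length(idx)) < keep) / keep,
                             nFeat, length(idx))
        fwd <- cnnForward(params, arch, Xb, dropMask, keepCache = TRUE,
                          M1 = M1b)
        loss <- halfMseLoss(fwd$pred, yb)
        if (!is.finite(loss))
          stop(sprintf("trainNetwork: non-finite loss at epoch %d", epoch))
        losses <- c(losses, loss)
        grads <- cnnBackward(params, arch, fwd, yb, dropMask)
        upd <- adamStep(params, grads, state, hp@learningRate, hp@l2Lambda)
        params <- upd$params
        state <- upd$state
      }
      history[epoch] <- mean(losses)
    }
  })
  net@params <- params
  net@trained <- TRUE
  net@lossHistory <- history
  net
}

#' Predict RBC content for a list of slices
#'
#' Deterministic forward pass (dropout disabled); one prediction per slice,
#' order preserved.
#'
#' @param net a [ThrombusNet-class].
#' @param sliceList list of canvas-standardized [SliceImage-class].
#' @param batchSize internal forward batch size.
#' @return numeric vector of predicted RBC percentages.
#' @export
predictSlices <- function(net, sliceList, batchSize = 256L) {
  N <- length(sliceList)
  if (!N) return(numeric())
  X <- slicesToArray(sliceList, net@arch@inputShape)
  out <- numeric(N)
  for (start in seq(1L, N, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, N)
    out[idx] <- cnnForward(net@params, net@arch,
                           X[, , idx, , drop = FALSE])$pred
  }
  out
}

#' Hyperparameter grid search over cross-validated MAE
#'
#' Runs the full grouped cross-validation for every candidate
#' [HyperParams-class] and returns the candidate minimizing the pooled
#' thrombus-level mean absolute error, with the full score table. Ties are
#' broken by grid enumeration order. By default every candidate reuses the
#' same fold assignment as the final evaluation; `nested = TRUE` derives a
#' distinct fold seed per candidate instead.
#'
#' @param cohort a preprocessed or raw [ThrombusCohort-class].
#' @param grid list of [HyperParams-class] candidates.
#' @param arch an [ArchConfig-class].
#' @param augConfig an [AugmentConfig-class] or `NULL` for the original
#'   (non-augmented) pipeline.
#' @param evalConfig an [EvalConfig-class].
#' @param nested logical; use a different fold split per candidate.
#' @return list with `best` ([HyperParams-class]), `bestIndex`, and
#'   `scores` (data.frame of pooled MAE and accuracy per candidate).
#' @export
gridSearch <- function(cohort, grid, arch = ArchConfig(), augConfig = NULL,
                       evalConfig = EvalConfig(), nested = FALSE) {
  if (!length(grid)) stop("gridSearch: empty grid")
  scores <- data.frame(index = seq_along(grid), thrombusMae = NA_real_,
                       thrombusAccuracy = NA_real_)
  reports <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    ec <- evalConfig
    if (nested) ec@seed <- deriveSeed(evalConfig@seed, 1000L + i)
    rep_i <- runCrossValidation(cohort, arch = arch, hp = grid[[i]],
                                augConfig = augConfig, evalConfig = ec)
    tm <- rep_i@metrics$thrombusRegression
    scores$thrombusMae[i] <- tm$mae
    scores$thrombusAccuracy[i] <- tm$accuracy
    reports[[i]] <- rep_i
  }
  best <- which.min(scores$thrombusMae)
  list(best = grid[[best]], bestIndex = best, scores = scores,
       reports = reports)
}
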