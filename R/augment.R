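## Training-set augmentation: input sampling equalization, dataset
## duplication, and random geometric transformation. All randomness is
## drawn from R's ambient RNG stream; augmentTrainingSet() scopes it under
## the AugmentConfig seed so augmentation never perturbs other stages.

#' Input sampling equalization
#'
#' Bins training slices by RBC content into `[k b, (k+1) b)` intervals
#' (edges anchored at 0) and oversamples every under-represented bin,
#' uniformly with replacement among its members, until its count equals
#' `floor(cMax / c) * c`, where `cMax` is the size of the most represented
#' bin. The most represented bin is unchanged; output order is all
#' original slices first, then the resampled copies.
#'
#' @param sliceList list of [SliceImage-class].
#' @param rbc numeric vector of per-slice RBC percentages (same length).
#' @param binWidth bin width in RBC percentage points (default 5).
#' @return list with `slices`, `rbc`, and `sourceIndex` (index into the
#'   input list for every output slice).
#' @export
equalizeSampling <- function(sliceList, rbc, binWidth = 5) {
  n <- length(sliceList)
  stopifnot(n >= 1L, length(rbc) == n)
  bin <- floor(rbc / binWidth)
  counts <- table(bin)
  cMax <- max(counts)
  extraIdx <- integer()
  for (bName in names(counts)) {
    c0 <- counts[[bName]]
    target <- (cMax %/% c0) * c0
    if (target > c0) {
      members <- which(bin == as.numeric(bName))
      extraIdx <- c(extraIdx,
                    members[sample.int(length(members), target - c0,
                                       replace = TRUE)])
    }
  }
  idx <- c(seq_len(n), extraIdx)
  out <- sliceList[idx]
  if (length(extraIdx)) {
    for (j in seq_along(extraIdx)) {
      k <- n + j
      out[[k]]@augmentId <- paste0(out[[k]]@augmentId, ".eq", j)
    }
  }
  list(slices = out, rbc = rbc[idx], sourceIndex = idx)
}

#' Duplicate a training set
#'
#' Concatenates `factor` copies of the slice list; copies carry distinct
#' augmentation-instance tags but identical pixel content.
#'
#' @param sliceList list of [SliceImage-class].
#' @param factor integer >= 1.
#' @return list of length `factor * length(sliceList)`.
#' @export
duplicateSet <- function(sliceList, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("duplicateSet: factor must be >= 1")
  if (!length(sliceList) || factor == 1L) return(sliceList)
  out <- sliceList
  for (k in 2:factor) {
    copyK <- lapply(sliceList, function(s) {
      s@augmentId <- paste0(s@augmentId, ".d", k)
      s
    })
    out <- c(out, copyK)
  }
  out
}

## Build the 2x2 forward map (reflect -> scale -> shear -> rotate; the
## integer translation is handled in the inverse's offset).
composeAffine <- function(rot, reflectX, reflectY, scale, shear) {
  F <- diag(c(if (reflectY) -1 else 1, if (reflectX) -1 else 1))
  S <- diag(c(scale, scale))
  Sh <- matrix(c(1, 0, tan(shear * pi / 180), 1), 2, 2)
  th <- rot * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  R %*% Sh %*% S %*% F
}

#' Apply one random geometric transformation
#'
#' Samples a rotation, integer translation, per-axis reflections (each with
#' probability 0.5 for the configured axes), an isotropic scale factor and
#' a horizontal shear from the configured ranges and composes them as a
#' single affine map about the canvas center, applied in the order
#' reflect, scale, shear, rotate, translate. All three channels are
#' resampled bilinearly with the shared map; the mask is resampled with the
#' same map and re-binarized at 0.5, and channels are re-masked so the
#' background stays exactly 0. If the transformed mask is empty the
#' parameters are redrawn (up to 10 retries) before failing.
#'
#' Draws from the ambient RNG stream; call `set.seed()` beforehand for a
#' reproducible single transform, or let [augmentTrainingSet] scope the
#' stream under its configured seed.
#'
#' @param slice a [SliceImage-class] on the standard canvas.
#' @param config an [AugmentConfig-class].
#' @return The transformed [SliceImage-class] (same dimensions).
#' @export
randomTransform <- function(slice, config) {
  h <- nrow(slice@mask); w <- ncol(slice@mask)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  for (attempt in seq_len(10L)) {
    rot <- runif(1, config@rotationRange[1L], config@rotationRange[2L])
    tmax <- config@translationMax
    tx <- if (tmax > 0L) sample(seq(-tmax, tmax), 1L) else 0L
    ty <- if (tmax > 0L) sample(seq(-tmax, tmax), 1L) else 0L
    reflectX <- "x" %in% config@reflectAxes && runif(1) < 0.5
    reflectY <- "y" %in% config@reflectAxes && runif(1) < 0.5
    scale <- runif(1, config@scaleRange[1L], config@scaleRange[2L])
    shear <- runif(1, config@shearRange[1L], config@shearRange[2L])
    A <- composeAffine(rot, reflectX, reflectY, scale, shear)
    identityMap <- rot == 0 && tx == 0L && ty == 0L && !reflectX &&
      !reflectY && scale == 1 && shear == 0
    if (identityMap) return(slice)     # exact: bilinear at integer offsets
    inv <- solve(A)
    ## target q: q = A (p - c) + c + t  =>  p = c + inv (q - c - t)
    shiftX <- cx + tx; shiftY <- cy + ty
    resamp <- function(img) {
      x <- matrix(seq_len(w) - shiftX, h, w, byrow = TRUE)
      y <- matrix(seq_len(h) - shiftY, h, w)
      sx <- inv[1L, 1L] * x + inv[1L, 2L] * y + cx
      sy <- inv[2L, 1L] * x + inv[2L, 2L] * y + cy
      bilinearGather(img, sy, sx)
    }
    newMask <- (resamp(slice@mask) >= 0.5) * 1
    if (sum(newMask) >= 1) {
      ch <- slice@channels
      for (k in 1:3) ch[, , k] <- resamp(slice@channels[, , k]) * newMask
      slice@channels <- ch
      slice@mask <- newMask
      slice@augmentId <- paste0(slice@augmentId, ".t")
      return(slice)
    }
  }
  stop("randomTransform: transformed mask empty after 10 retries")
}

bilinearGather <- function(img, sy, sx) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  gather <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    idx <- pmin(pmax(yy, 1), h) + (pmin(pmax(xx, 1), w) - 1) * h
    v <- img[idx]
    v[!ok] <- 0
    matrix(v, h, w)
  }
  gather(y0, x0) * (1 - fy) * (1 - fx) +
    gather(y0, x0 + 1) * (1 - fy) * fx +
    gather(y0 + 1, x0) * fy * (1 - fx) +
    gather(y0 + 1, x0 + 1) * fy * fx
}

#' Full three-component training-set augmentation
#'
#' Applies input sampling equalization, then whole-set duplication, then
#' one random geometric transformation per resulting slice (duplication
#' before transformation, so every slice seen by the network is unique).
#' The RNG stream is scoped under `config@seed`: the same inputs and seed
#' always produce the identical augmented set.
#'
#' @param sliceList list of [SliceImage-class] (training slices only).
#' @param rbc per-slice RBC percentages.
#' @param config an [AugmentConfig-class].
#' @return list with `slices` and `rbc` (aligned).
#' @export
augmentTrainingSet <- function(sliceList, rbc, config) {
  stopifnot(length(sliceList) >= 1L)
  validObject(config)
  withSeed(config@seed, {
    eq <- equalizeSampling(sliceList, rbc, config@binWidth)
    dup <- duplicateSet(eq$slices, config@duplicationFactor)
    dupRbc <- rep(eq$rbc, times = config@duplicationFactor)
    out <- lapply(dup, randomTransform, config = config)
    list(slices = out, rbc = dupRbc)
  })
}
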