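## Synthetic thrombus cohort generator.
##
## Signal model: each thrombus has a ground-truth RBC area fraction f and a
## latent "oxygenation" factor w (lognormal, shared by R2* and QSM). On each
## slice an elliptical mask is drawn and a smoothed Gaussian random field is
## thresholded at the (1 - f) quantile of its in-mask values, giving a
## binary RBC-patch field whose in-mask area fraction equals f up to pixel
## quantization. R2* and QSM take their "high" tissue value scaled by w
## inside patches and their "low" value outside, plus noise; the late-echo
## GRE magnitude follows monoexponential decay m0 * exp(-teLate * R2*).
## Because w multiplies the patch amplitude, thrombus-mean R2*/QSM are
## confounded by oxygenation while the patch area fraction is not: the RBC
## target is recoverable from spatial texture but not from channel means,
## mirroring the ex vivo observation that summary imaging values do not
## correlate with histological RBC content.

## Weighted least-squares fit of a scaled Beta to the calibration
## statistics: the three inner quantile anchors (min/max fix the support)
## plus the naive cohort-median predictor's accuracy and absolute error
## (targets naiveAcc / naiveMae), which pin down the shape near the median
## that three quantiles alone leave loose. The weights favor the median
## anchor and the naive moments, the statistics the generator is judged
## by; the quartile anchors act as soft constraints.
fitRbcBeta <- function(anchors, tol = 10, naiveAcc = 0.48, naiveMae = 10.4) {
  lo <- anchors[1L]; hi <- anchors[5L]
  rng <- hi - lo
  target <- (anchors[2:4] - lo) / rng
  obj <- function(p) {
    a <- exp(p[1L]); b <- exp(p[2L])
    q <- stats::qbeta(c(0.25, 0.5, 0.75), a, b)
    m <- q[2L]
    acc <- stats::pbeta(pmin(m + tol / rng, 1), a, b) -
      stats::pbeta(pmax(m - tol / rng, 0), a, b)
    mae <- stats::integrate(function(x) abs(x - m) * stats::dbeta(x, a, b),
                            0, 1)$value * rng
    sum((q - target)^2) + 15 * (q[2L] - target[2L])^2 +
      20 * (acc - naiveAcc)^2 + 10 * ((mae - naiveMae) / rng)^2
  }
  fit <- optim(c(log(2), log(2)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  list(shape1 = exp(fit$par[1L]), shape2 = exp(fit$par[2L]),
       lo = lo, hi = hi)
}

## Deterministic near-even slice allocation ("fixed-list"): the first
## (totalSlices mod nThrombi) thrombi receive one extra slice. For the
## 48-thrombus / 188-slice layout this yields 44 x 4 + 4 x 3.
allocateSlices <- function(config) {
  n <- config@nThrombi; total <- config@totalSlices
  if (config@sliceAllocation == "fixed-list") {
    base <- total %/% n
    extra <- total - base * n
    counts <- rep(base, n)
    if (extra > 0L) counts[seq_len(extra)] <- base + 1L
  } else { # poisson-adjusted
    counts <- 1L + rpois(n, max(total / n - 1, 0.01))
    ## adjust deterministically to the exact total, keeping counts >= 1
    diffn <- total - sum(counts)
    i <- 1L
    while (diffn != 0L) {
      if (diffn > 0L) { counts[i] <- counts[i] + 1L; diffn <- diffn - 1L }
      else if (counts[i] > 1L) { counts[i] <- counts[i] - 1L; diffn <- diffn + 1L }
      i <- if (i == n) 1L else i + 1L
    }
  }
  as.integer(counts)
}

## Separable Gaussian smoothing with reflected edges; sigma in pixels.
gaussianSmooth <- function(z, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  smooth1 <- function(m) { # along rows (dim 1)
    n <- nrow(m)
    idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    mp <- m[idx, , drop = FALSE]
    out <- 0
    for (j in seq_along(k)) out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(z))))
}

## Random perturbed-ellipse mask on the canvas, area ~ U(300, 2000) px
## (clipped so the bounding box fits the canvas with a 1-pixel margin).
randomMask <- function(canvas) {
  h <- canvas[1L]; w <- canvas[2L]
  area <- runif(1, 300, 2000)
  rho <- exp(runif(1, log(0.6), log(1.6)))   # aspect ratio
  a <- sqrt(area * rho / pi)                 # semi-axis along rows
  b <- sqrt(area / (rho * pi))               # semi-axis along cols
  a <- min(a, (h - 3) / 2); b <- min(b, (w - 3) / 2)
  eps <- runif(1, 0, 0.15)                   # perimeter perturbation
  lobes <- sample(2:5, 1)
  phase <- runif(1, 0, 2 * pi)
  tilt <- runif(1, 0, pi)
  yc <- (h + 1) / 2; xc <- (w + 1) / 2
  y <- matrix(seq_len(h) - yc, h, w)
  x <- matrix(seq_len(w) - xc, h, w, byrow = TRUE)
  yr <- cos(tilt) * y + sin(tilt) * x
  xr <- -sin(tilt) * y + cos(tilt) * x
  theta <- atan2(yr / a, xr / b)
  rad <- sqrt((yr / a)^2 + (xr / b)^2)
  mask <- (rad <= 1 + eps * sin(lobes * theta + phase)) * 1
  if (sum(mask) < 1) mask[round(yc), round(xc)] <- 1
  mask
}

#' Render one synthetic thrombus slice
#'
#' Draws a perturbed-ellipse mask, a thresholded correlated random field of
#' RBC patches whose in-mask area fraction equals `rbcPercent / 100` (up to
#' pixel quantization), and the three channels of the signal model (see the
#' package vignette). Fully deterministic given `seed`.
#'
#' @param thrombusId character ID stored in the slice.
#' @param sliceIndex integer slice index.
#' @param rbcPercent ground-truth RBC percentage in \[0, 100\].
#' @param oxygenation positive latent amplitude factor.
#' @param config a [GeneratorConfig-class].
#' @param seed integer seed for this slice.
#' @return A [SliceImage-class].
#' @export
renderSlice <- function(thrombusId, sliceIndex, rbcPercent, oxygenation,
                        config, seed) {
  stopifnot(rbcPercent >= 0, rbcPercent <= 100, oxygenation > 0)
  cal <- config@calibration
  withSeed(seed, {
    h <- config@canvas[1L]; w <- config@canvas[2L]
    mask <- randomMask(config@canvas)
    field <- gaussianSmooth(matrix(rnorm(h * w), h, w), config@patchCorrLen)
    inIdx <- which(mask == 1)
    nPatch <- round(rbcPercent / 100 * length(inIdx))
    patch <- matrix(0, h, w)
    if (nPatch > 0) {
      ord <- order(field[inIdx], decreasing = TRUE)
      patch[inIdx[ord[seq_len(nPatch)]]] <- 1
    }
    ns <- config@noiseSd
    r2star <- cal[["r2sLow"]] +
      patch * (cal[["r2sHigh"]] * oxygenation - cal[["r2sLow"]])
    if (ns[[1L]] > 0) r2star <- r2star + matrix(rnorm(h * w, 0, ns[[1L]]), h, w)
    qsm <- cal[["qsmLow"]] +
      patch * (cal[["qsmHigh"]] * oxygenation - cal[["qsmLow"]])
    if (ns[[2L]] > 0) qsm <- qsm + matrix(rnorm(h * w, 0, ns[[2L]]), h, w)
    gre <- cal[["m0"]] * exp(-config@teLate * (cal[["r2sLow"]] +
      patch * (cal[["r2sHigh"]] * oxygenation - cal[["r2sLow"]])))
    if (ns[[3L]] > 0) gre <- gre + matrix(rnorm(h * w, 0, ns[[3L]]), h, w)
    gre <- pmax(gre, 0)
    channels <- array(0, dim = c(h, w, 3L),
                      dimnames = list(NULL, NULL, c("r2star", "qsm", "gre")))
    channels[, , 1L] <- r2star * mask
    channels[, , 2L] <- qsm * mask
    channels[, , 3L] <- gre * mask
    new("SliceImage", thrombusId = thrombusId,
        sliceIndex = as.integer(sliceIndex), channels = channels,
        mask = mask)
  })
}

#' Generate a synthetic thrombus cohort
#'
#' Draws per-thrombus ground-truth RBC percentages from a scaled Beta
#' distribution least-squares fitted to the configured quantile anchors,
#' lognormal latent oxygenation factors, allocates slices per thrombus, and
#' renders every slice. Identical configuration (including seed) yields a
#' bit-identical cohort.
#'
#' @param config a [GeneratorConfig-class]; invalid configurations raise an
#'   error naming the offending field.
#' @return A [ThrombusCohort-class].
#' @examples
#' cfg <- GeneratorConfig(nThrombi = 2L, totalSlices = 3L, seed = 7L)
#' coh <- generateCohort(cfg)
#' nThrombi(coh); nSlices(coh)
#' @export
generateCohort <- function(config) {
  validObject(config)
  fit <- fitRbcBeta(config@rbcQuantiles)
  n <- config@nThrombi
  core <- withSeed(config@seed, {
    rbc <- fit$lo + (fit$hi - fit$lo) * rbeta(n, fit$shape1, fit$shape2)
    oxy <- rlnorm(n, meanlog = 0, sdlog = config@oxygenationSd)
    counts <- allocateSlices(config)
    list(rbc = rbc, oxy = oxy, counts = counts)
  })
  thrombi <- data.frame(
    thrombusId = sprintf("T%04d", seq_len(n)),
    rbcPercent = core$rbc, oxygenation = core$oxy,
    nSlices = core$counts, stringsAsFactors = FALSE)
  slices <- vector("list", sum(core$counts))
  g <- 0L
  for (i in seq_len(n)) {
    for (s in seq_len(core$counts[i])) {
      g <- g + 1L
      slices[[g]] <- renderSlice(thrombi$thrombusId[i], s,
                                 thrombi$rbcPercent[i], thrombi$oxygenation[i],
                                 config, deriveSeed(config@seed, 100L + g))
    }
  }
  new("ThrombusCohort", thrombi = thrombi, slices = slices, config = config,
      metadata = list(seed = config@seed,
                      betaFit = fit[c("shape1", "shape2")],
                      configHash = configHash(config)))
}

#' Cohort-level summary statistics
#'
#' Thrombus-level median / IQR / min / max of the ground-truth RBC
#' percentage and of the in-mask mean R2* and QSM values (each thrombus's
#' slices averaged), plus the Pearson correlation between thrombus-mean
#' imaging values and RBC content. With a single thrombus the correlations
#' are undefined and returned as `NA` with `correlationDefined = FALSE`.
#'
#' @param cohort a [ThrombusCohort-class].
#' @return A list with elements `rbc`, `r2star`, `qsm` (each median / q1 /
#'   q3 / min / max), `rR2s`, `rQsm`, `correlationDefined`, `nThrombi`.
#' @export
cohortSummary <- function(cohort) {
  if (nrow(cohort@thrombi) < 1L) stop("empty cohort")
  ids <- vapply(cohort@slices, function(s) s@thrombusId, "")
  meanIn <- function(s, ch) {
    m <- s@mask == 1
    mean(s@channels[, , ch][m])
  }
  r2s <- vapply(cohort@slices, meanIn, 0, ch = "r2star")
  qsm <- vapply(cohort@slices, meanIn, 0, ch = "qsm")
  thr <- cohort@thrombi
  thrR2s <- tapply(r2s, ids, mean)[thr$thrombusId]
  thrQsm <- tapply(qsm, ids, mean)[thr$thrombusId]
  fivenum2 <- function(x) c(median = median(x),
                            q1 = unname(quantile(x, 0.25)),
                            q3 = unname(quantile(x, 0.75)),
                            min = min(x), max = max(x))
  defined <- nrow(thr) >= 2L && sd(thr$rbcPercent) > 0
  list(rbc = fivenum2(thr$rbcPercent),
       r2star = fivenum2(as.numeric(thrR2s)),
       qsm = fivenum2(as.numeric(thrQsm)),
       rR2s = if (defined) cor(thrR2s, thr$rbcPercent) else NA_real_,
       rQsm = if (defined) cor(thrQsm, thr$rbcPercent) else NA_real_,
       correlationDefined = defined,
       nThrombi = nrow(thr))
}
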