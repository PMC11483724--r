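## Preprocessing: pooled z-score normalization over in-mask pixels and
## placement on the fixed 49 x 56 network canvas.

#' Pooled per-channel normalization statistics
#'
#' Computes, per channel, the mean and population standard deviation
#' (divide-by-N) of the pooled in-mask pixels of the given slices. This is
#' the z-score reference derived from all segmented thrombi in the default
#' pipeline; pass a training fold's slices for the leakage-free variant.
#'
#' @param sliceList list of [SliceImage-class] (>= 1 slice; pooled in-mask
#'   pixel count >= 2).
#' @return A [NormalizationStats-class].
#' @export
computeNormStats <- function(sliceList) {
  if (!length(sliceList)) stop("computeNormStats: need at least one slice")
  vals <- lapply(1:3, function(ch)
    unlist(lapply(sliceList, function(s) s@channels[, , ch][s@mask == 1]),
           use.names = FALSE))
  n <- length(vals[[1L]])
  if (n < 2L) stop("computeNormStats: pooled in-mask pixel count must be >= 2")
  mu <- vapply(vals, mean, 0)
  sdp <- vapply(vals, function(v) sqrt(mean((v - mean(v))^2)), 0)
  if (any(sdp <= 0)) {
    ch <- c("r2star", "qsm", "gre")[which(sdp <= 0)]
    stop("computeNormStats: degenerate channel (zero pooled variance): ",
         paste(ch, collapse = ", "))
  }
  new("NormalizationStats", mean = mu, sd = sdp,
      thrombusIds = unique(vapply(sliceList, function(s) s@thrombusId, "")),
      nPixels = as.integer(n))
}

#' z-score normalize one slice
#'
#' Maps each in-mask pixel x to (x - mean) / sd per channel; out-of-mask
#' pixels are set to exactly 0 so the background carries no intensity
#' information.
#'
#' @param slice a [SliceImage-class].
#' @param stats a [NormalizationStats-class].
#' @return The normalized [SliceImage-class].
#' @export
normalizeSlice <- function(slice, stats) {
  validObject(stats)
  ch <- slice@channels
  for (k in 1:3)
    ch[, , k] <- ((ch[, , k] - stats@mean[k]) / stats@sd[k]) * slice@mask
  slice@channels <- ch
  slice
}

#' Undo z-score normalization (in-mask pixels)
#'
#' @param slice a normalized [SliceImage-class].
#' @param stats the [NormalizationStats-class] used to normalize.
#' @return The de-normalized [SliceImage-class] (background stays 0).
#' @export
denormalizeSlice <- function(slice, stats) {
  ch <- slice@channels
  for (k in 1:3)
    ch[, , k] <- (ch[, , k] * stats@sd[k] + stats@mean[k]) * slice@mask
  slice@channels <- ch
  slice
}

#' Place a slice on the fixed network canvas
#'
#' Crops the foreground (mask) bounding box and zero-pads it so that it is
#' centered on a `height` x `width` canvas; when centering leaves an odd
#' pixel the extra padding goes to the bottom/right (the foreground sits
#' toward the top-left). The mask is transformed identically. Idempotent.
#'
#' @param slice a [SliceImage-class].
#' @param height,width canvas size in pixels (default 49 x 56).
#' @return A [SliceImage-class] of exactly (height, width, 3).
#' @export
standardizeCanvas <- function(slice, height = 49L, width = 56L) {
  m <- slice@mask
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  bh <- diff(range(rows)) + 1L
  bw <- diff(range(cols)) + 1L
  if (bh > height || bw > width)
    stop(sprintf(paste0("standardizeCanvas: foreground bounding box ",
                        "(%d x %d) exceeds the %d x %d canvas"),
                 bh, bw, height, width))
  top <- (height - bh) %/% 2L
  left <- (width - bw) %/% 2L
  ch <- array(0, dim = c(height, width, 3L),
              dimnames = dimnames(slice@channels))
  newMask <- matrix(0, height, width)
  rIdx <- top + seq_len(bh)
  cIdx <- left + seq_len(bw)
  for (k in 1:3)
    ch[rIdx, cIdx, k] <- slice@channels[rows[1L]:rows[length(rows)],
                                        cols[1L]:cols[length(cols)], k]
  newMask[rIdx, cIdx] <- m[rows[1L]:rows[length(rows)],
                           cols[1L]:cols[length(cols)]]
  slice@channels <- ch
  slice@mask <- newMask
  slice
}

#' Preprocess a whole cohort for the network
#'
#' Standardizes every slice onto the network canvas and, when `stats` is
#' not supplied, computes pooled normalization statistics from the
#' canvas-standardized slices of the whole cohort before normalizing.
#'
#' @param cohort a [ThrombusCohort-class].
#' @param stats optional [NormalizationStats-class] to reuse.
#' @param height,width canvas size.
#' @return list with `cohort` (preprocessed) and `stats`.
#' @export
preprocessCohort <- function(cohort, stats = NULL, height = 49L,
                             width = 56L) {
  std <- lapply(cohort@slices, standardizeCanvas, height = height,
                width = width)
  if (is.null(stats)) stats <- computeNormStats(std)
  cohort@slices <- lapply(std, normalizeSlice, stats = stats)
  list(cohort = cohort, stats = stats)
}
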