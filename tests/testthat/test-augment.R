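# Three-component augmentation scheme.

# Independent oracle for the equalization rule: per-bin target counts.
equalizationOracle <- function(counts) {
  cmax <- max(counts)
  (cmax %/% counts) * counts
}

dummySlices <- function(rbc) {
  lapply(seq_along(rbc), function(i)
    flatSlice(values = c(i, i, i), id = sprintf("T%04d", i)))
}

test_that("equalization matches the floor-multiple rule on the worked example", {
  # bins with counts {10, 4, 7} -> {10, 8, 7}
  rbc <- c(runif(10, 0, 4.9), runif(4, 5, 9.9), runif(7, 10, 14.9))
  set.seed(1)
  out <- equalizeSampling(dummySlices(rbc), rbc, binWidth = 5)
  expect_equal(as.integer(table(floor(out$rbc / 5))), c(10L, 8L, 7L))
  # originals first, in input order
  expect_equal(out$sourceIndex[1:21], 1:21)
})

test_that("equalized bin counts equal floor(cmax/c) * c for random count vectors", {
  set.seed(42)
  for (rep in 1:25) {
    nBins <- sample(2:8, 1)
    counts <- sample(1:12, nBins, replace = TRUE)
    rbc <- unlist(lapply(seq_len(nBins), function(b)
      runif(counts[b], (b - 1) * 5, b * 5 - 0.01)))
    out <- equalizeSampling(dummySlices(rbc), rbc, binWidth = 5)
    got <- as.integer(table(factor(floor(out$rbc / 5), levels = 0:(nBins - 1))))
    expect_equal(got, unname(equalizationOracle(counts)))
    # never removes slices; copies resample existing members of the bin
    expect_true(all(seq_along(rbc) %in% out$sourceIndex))
    expect_true(all(floor(rbc[out$sourceIndex] / 5) == floor(out$rbc / 5)))
  }
})

test_that("equal bins and single bins are fixed points of equalization", {
  rbc <- c(1, 2, 7, 8, 12, 13)      # three bins of 2
  out <- equalizeSampling(dummySlices(rbc), rbc, binWidth = 5)
  expect_equal(out$rbc, rbc)
  one <- equalizeSampling(dummySlices(c(1, 2, 3)), c(1, 2, 3), binWidth = 5)
  expect_equal(one$sourceIndex, 1:3)
})

test_that("duplication multiplies the set size exactly and tags copies", {
  sl <- dummySlices(rep(10, 4))
  expect_length(duplicateSet(sl, 5L), 20L)
  expect_identical(duplicateSet(sl, 1L), sl)
  expect_length(duplicateSet(list(), 3L), 0L)
  expect_error(duplicateSet(sl, 0L), "factor")
  dup <- duplicateSet(sl, 2L)
  expect_identical(dup[[5L]]@channels, sl[[1L]]@channels)
  expect_false(identical(dup[[5L]]@augmentId, sl[[1L]]@augmentId))
})

test_that("identity transform ranges return the slice exactly", {
  s <- standardizeCanvas(slices(smallCohort())[[2L]])
  cfg <- identityAugmentConfig()
  set.seed(4)
  out <- randomTransform(s, cfg)
  expect_identical(out@channels, s@channels)
  expect_identical(out@mask, s@mask)
})

test_that("reflection is an involution of the resampling map", {
  s <- standardizeCanvas(slices(smallCohort())[[3L]])
  A <- thromboCNN:::composeAffine(0, TRUE, FALSE, 1, 0)
  h <- nrow(s@mask); w <- ncol(s@mask)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  reflectOnce <- function(img) {
    inv <- solve(A)
    x <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
    y <- matrix(seq_len(h) - cy, h, w)
    thromboCNN:::bilinearGather(img, inv[2, 1] * x + inv[2, 2] * y + cy,
                                inv[1, 1] * x + inv[1, 2] * y + cx)
  }
  twice <- reflectOnce(reflectOnce(s@channels[, , 1L]))
  expect_equal(twice, s@channels[, , 1L], tolerance = 1e-12)
  once <- reflectOnce(s@channels[, , 1L])
  expect_false(isTRUE(all.equal(once, s@channels[, , 1L])))
})

test_that("random transforms preserve canvas shape and zero background", {
  s <- standardizeCanvas(slices(smallCohort())[[4L]])
  cfg <- AugmentConfig(seed = 1L)
  set.seed(8)
  for (i in 1:5) {
    out <- randomTransform(s, cfg)
    expect_equal(dim(out@channels), dim(s@channels))
    expect_true(sum(out@mask) >= 1)
    for (k in 1:3)
      expect_true(all(out@channels[, , k][out@mask == 0] == 0))
  }
})

test_that("full augmentation path yields the derived counts", {
  # one bin of 10 slices, defaults -> 10 equalized -> x5 = 50
  rbc <- runif(10, 30, 34.9)
  pp <- lapply(dummySlices(rbc), standardizeCanvas)
  out <- augmentTrainingSet(pp, rbc, AugmentConfig(seed = 2L))
  expect_length(out$slices, 50L)
  # bins {10, 4, 7}, factor 5 -> (10 + 8 + 7) * 5 = 125
  rbc2 <- c(runif(10, 0, 4.9), runif(4, 5, 9.9), runif(7, 10, 14.9))
  pp2 <- lapply(dummySlices(rbc2), standardizeCanvas)
  out2 <- augmentTrainingSet(pp2, rbc2, AugmentConfig(seed = 2L))
  expect_length(out2$slices, 125L)
  expect_length(out2$rbc, 125L)
})

test_that("identity-path augmentation returns the input set unchanged", {
  rbc <- c(31, 32, 33, 34)           # a single bin
  pp <- lapply(dummySlices(rbc), standardizeCanvas)
  out <- augmentTrainingSet(pp, rbc, identityAugmentConfig(seed = 5L))
  expect_length(out$slices, 4L)
  for (i in 1:4)
    expect_identical(out$slices[[i]]@channels, pp[[i]]@channels)
  expect_equal(out$rbc, rbc)
})

test_that("augmentation is reproducible under a fixed seed", {
  coh <- smallCohort()
  pp <- lapply(slices(coh)[1:8], standardizeCanvas)
  rbc <- rep(c(20, 40), each = 4)
  cfg <- AugmentConfig(duplicationFactor = 2L, seed = 33L)
  a <- augmentTrainingSet(pp, rbc, cfg)
  b <- augmentTrainingSet(pp, rbc, cfg)
  expect_length(a$slices, length(b$slices))
  for (i in seq_along(a$slices))
    expect_identical(a$slices[[i]]@channels, b$slices[[i]]@channels)
  # transformed copies are pixel-distinct from their sources
  expect_false(identical(a$slices[[9L]]@channels, pp[[1L]]@channels))
})
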