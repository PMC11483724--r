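# CNN construction, loss, training, prediction, grid search.

test_that("default architecture has conv widths 16/16/32 and a scalar head", {
  net <- buildNetwork(ArchConfig(), seed = 1L)
  expect_equal(ncol(net@params$W1), 16L)
  expect_equal(ncol(net@params$W2), 16L)
  expect_equal(ncol(net@params$W3), 32L)
  expect_equal(ncol(net@params$Wd), 1L)
  s <- standardizeCanvas(slices(smallCohort())[[1L]])
  expect_length(predictSlices(net, list(s)), 1L)
})

test_that("parameter count of the default architecture is stable", {
  # 3x3x3x16 + 16 + 3x3x16x16 + 16 + 3x3x16x32 + 32 + 12*14*32 + 1
  expect_equal(nParameters(buildNetwork(ArchConfig(), seed = 1L)), 12785L)
})

test_that("initialization is a pure function of the seed", {
  a <- buildNetwork(ArchConfig(), seed = 7L)
  b <- buildNetwork(ArchConfig(), seed = 7L)
  c <- buildNetwork(ArchConfig(), seed = 8L)
  expect_identical(a@params, b@params)
  expect_false(identical(a@params$W1, c@params$W1))
})

test_that("half MSE matches its definition and a brute-force oracle", {
  expect_equal(halfMseLoss(c(1, 2), c(1, 2)), 0)
  expect_equal(halfMseLoss(5, 3), 2)              # 2^2 / 2
  expect_equal(halfMseLoss(c(3, 5), c(3, 3)), 1)  # mean of {0, 2}
  expect_error(halfMseLoss(1:3, 1:2), "equal length")
  set.seed(9)
  for (i in 1:5) {
    p <- rnorm(17, 50, 20); y <- rnorm(17, 50, 20)
    acc <- 0
    for (j in seq_along(p)) acc <- acc + (p[j] - y[j])^2 / 2
    expect_equal(halfMseLoss(p, y), acc / length(p), tolerance = 1e-12)
  }
})

test_that("zero training epochs return the network unchanged", {
  net <- buildNetwork(ArchConfig(), seed = 2L)
  sl <- lapply(slices(smallCohort())[1:3], standardizeCanvas)
  out <- trainNetwork(net, sl, c(30, 40, 50), HyperParams(nEpochs = 0L))
  expect_identical(out@params, net@params)
  expect_length(out@lossHistory, 0L)
})

test_that("training rejects empty sets and out-of-range targets", {
  net <- buildNetwork(ArchConfig(), seed = 2L)
  expect_error(trainNetwork(net, list(), numeric(), HyperParams()), "empty")
  sl <- lapply(slices(smallCohort())[1:2], standardizeCanvas)
  expect_error(trainNetwork(net, sl, c(50, 120), HyperParams()),
               "\\[0, 100\\]")
})

test_that("the network memorizes a 4-slice set without regularization", {
  pp <- preprocessCohort(smallCohort())
  sl <- slices(pp$cohort)[c(1L, 5L, 9L, 13L)]
  y <- c(20, 35, 50, 60)
  net <- buildNetwork(ArchConfig(), seed = 3L)
  hp <- HyperParams(batchSize = 4L, learningRate = 5e-3, nEpochs = 150L,
                    l2Lambda = 0, dropoutRate = 0, seed = 3L)
  net <- trainNetwork(net, sl, y, hp)
  expect_lt(tail(net@lossHistory, 1L), 0.01 * net@lossHistory[1L])
})

test_that("a huge L2 penalty crushes the weights and flattens predictions", {
  pp <- preprocessCohort(smallCohort())
  sl <- slices(pp$cohort)[1:4]
  y <- c(20, 35, 50, 60)
  net0 <- buildNetwork(ArchConfig(), seed = 4L)
  hp <- HyperParams(batchSize = 4L, learningRate = 2e-2, nEpochs = 200L,
                    l2Lambda = 1e4, dropoutRate = 0, seed = 4L)
  net <- trainNetwork(net0, sl, y, hp)
  expect_lt(mean(abs(net@params$W1)), 1e-3 * mean(abs(net0@params$W1)))
  expect_lt(mean(abs(net@params$W3)), 0.05 * mean(abs(net0@params$W3)))
  # with the penalized weights gone, only the (unpenalized) bias pathway
  # remains and every slice receives the same prediction
  p <- predictSlices(net, sl)
  expect_lt(diff(range(p)), 1e-3)
})

test_that("prediction is deterministic and batching-invariant", {
  net <- buildNetwork(ArchConfig(), seed = 5L)
  sl <- lapply(slices(smallCohort())[1:6], standardizeCanvas)
  p1 <- predictSlices(net, sl)
  p2 <- predictSlices(net, sl)
  expect_identical(p1, p2)
  one <- predictSlices(net, sl[3L])
  expect_equal(one, p1[3L], tolerance = 1e-10)
  dupBatch <- predictSlices(net, list(sl[[2L]], sl[[2L]]))
  expect_equal(dupBatch[1L], dupBatch[2L])
})

test_that("a zero-weight network predicts the output bias everywhere", {
  net <- buildNetwork(ArchConfig(), seed = 6L)
  net@params <- lapply(net@params, function(p) p * 0)
  net@params$bd <- 42
  sl <- lapply(slices(smallCohort())[1:4], standardizeCanvas)
  expect_equal(predictSlices(net, sl), rep(42, 4))
})

test_that("training reduces held-out error on a learnable synthetic cohort", {
  coh <- generateCohort(GeneratorConfig(nThrombi = 14L, totalSlices = 28L,
                                        seed = 41L))
  pp <- preprocessCohort(coh)
  ids <- vapply(slices(pp$cohort), function(s) s@thrombusId, "")
  truth <- rbcPercent(coh)
  y <- unname(truth[ids])
  test <- ids %in% thrombusData(coh)$thrombusId[1:4]
  net0 <- buildNetwork(ArchConfig(), seed = 7L)
  hp <- HyperParams(nEpochs = 12L, seed = 7L)
  net <- trainNetwork(net0, slices(pp$cohort)[!test], y[!test], hp)
  maeUntrained <- mean(abs(predictSlices(net0, slices(pp$cohort)[test]) - y[test]))
  maeTrained <- mean(abs(predictSlices(net, slices(pp$cohort)[test]) - y[test]))
  expect_lt(maeTrained, maeUntrained)
})

test_that("grid search returns the winner by pooled MAE with first-hit ties", {
  coh <- generateCohort(GeneratorConfig(nThrombi = 8L, totalSlices = 16L,
                                        seed = 51L))
  ec <- EvalConfig(kFolds = 2L, seed = 1L)
  hpTrained <- HyperParams(nEpochs = 8L, seed = 2L)
  hpNull <- HyperParams(nEpochs = 0L, seed = 2L)
  gs <- gridSearch(coh, list(hpNull, hpTrained), evalConfig = ec)
  # the trained point must beat the untrained (bias-zero) network
  expect_equal(gs$bestIndex, 2L)
  expect_equal(gs$scores$thrombusMae[2L],
               min(gs$scores$thrombusMae))
  # duplicate grid points tie-break to the first occurrence
  gsDup <- gridSearch(coh, list(hpTrained, hpTrained), evalConfig = ec)
  expect_equal(gsDup$bestIndex, 1L)
  expect_error(gridSearch(coh, list(), evalConfig = ec), "empty")
})
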