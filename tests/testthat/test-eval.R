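# Grouped cross-validation and the metric suite.

# Brute-force all-pairs AUC oracle (n <= 20 in the tests that use it).
aucByEnumeration <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("grouped split partitions thrombi into near-equal folds", {
  coh <- exvivoCohort()
  folds <- groupedKFoldSplit(coh, 8L, seed = 1L)
  expect_length(folds, 8L)
  expect_true(all(lengths(folds) == 6L))
  expect_setequal(unlist(folds), thrombusData(coh)$thrombusId)
  expect_equal(anyDuplicated(unlist(folds)), 0L)
  # function of the seed only
  expect_identical(folds, groupedKFoldSplit(coh, 8L, seed = 1L))
  expect_false(identical(folds, groupedKFoldSplit(coh, 8L, seed = 2L)))
})

test_that("remainder thrombi spread across folds by at most one", {
  coh <- generateCohort(GeneratorConfig(nThrombi = 5L, totalSlices = 5L,
                                        seed = 2L))
  folds <- groupedKFoldSplit(coh, 2L, seed = 3L)
  expect_setequal(lengths(folds), c(3L, 2L))
  expect_error(groupedKFoldSplit(coh, 6L, seed = 1L), "k must be")
})

test_that("thrombus aggregation is the median with midpoint rule", {
  expect_equal(aggregateThrombusPrediction(c(30, 35, 40)), 35)
  expect_equal(aggregateThrombusPrediction(c(30, 40)), 35)
  expect_equal(aggregateThrombusPrediction(42), 42)
  expect_error(aggregateThrombusPrediction(numeric()), "empty")
})

test_that("regression metrics match the worked examples", {
  m <- regressionMetrics(c(38, 38), c(30, 50), tol = 10)
  expect_equal(m$accuracy, 50)
  expect_equal(m$mae, 10)
  perfect <- regressionMetrics(c(10, 20, 30), c(10, 20, 30))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$pearsonR, 1)
  expect_equal(perfect$slope, 1)
  flat <- regressionMetrics(c(25, 25, 25), c(10, 20, 30))
  expect_equal(flat$slope, 0)
  expect_false(flat$correlationDefined)
  expect_true(is.na(flat$pearsonR))
})

test_that("regression metrics agree with brute-force recomputation", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    y <- runif(n, 10, 60); p <- y + rnorm(n, 0, 8)
    m <- regressionMetrics(p, y, tol = 10)
    acc <- 0; mae <- 0
    for (j in seq_len(n)) {
      acc <- acc + (abs(p[j] - y[j]) <= 10)
      mae <- mae + abs(p[j] - y[j])
    }
    expect_equal(m$accuracy, 100 * acc / n, tolerance = 1e-10)
    expect_equal(m$mae, mae / n, tolerance = 1e-10)
    expect_equal(m$pearsonR, cor(p, y), tolerance = 1e-10)
    beta <- sum((y - mean(y)) * (p - mean(p))) / sum((y - mean(y))^2)
    expect_equal(m$slope, beta, tolerance = 1e-10)
  }
})

test_that("widening the accuracy tolerance never decreases accuracy", {
  set.seed(15)
  y <- runif(30, 10, 60); p <- y + rnorm(30, 0, 10)
  accs <- vapply(c(2, 5, 10, 15, 25),
                 function(tol) regressionMetrics(p, y, tol)$accuracy, 0)
  expect_true(all(diff(accs) >= 0))
})

test_that("classification metrics match the worked examples", {
  perfect <- classificationMetrics(c(20, 50), c(20, 50), threshold = 38)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$auc, 1)
  const <- classificationMetrics(c(40, 40, 40, 40), c(20, 30, 45, 55),
                                 threshold = 38)
  expect_equal(const$auc, 0.5)    # all ties under the rank formulation
  # one positive/negative pair, both misclassified and mis-ranked
  worst <- classificationMetrics(c(45, 35), c(30, 50), threshold = 38)
  expect_equal(worst$accuracy, 0)
  expect_equal(worst$auc, 0)
})

test_that("truths exactly at the threshold are labeled RBC-rich", {
  m <- classificationMetrics(c(38, 10), c(38, 10), threshold = 38)
  expect_equal(m$trueLabel, c("RBC-rich", "RBC-poor"))
  expect_equal(m$predictedLabel, c("RBC-rich", "RBC-poor"))
})

test_that("rank AUC equals all-pairs enumeration including ties", {
  set.seed(16)
  for (i in 1:12) {
    n <- sample(4:20, 1)
    y <- runif(n, 10, 60)
    p <- round(y + rnorm(n, 0, 12), -1)   # rounding forces ties
    thr <- median(y) + runif(1, -5, 5)
    if (all(y < thr) || all(y >= thr)) next
    m <- classificationMetrics(p, y, threshold = thr)
    expect_equal(m$auc, aucByEnumeration(-p, y < thr), tolerance = 1e-10)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(23)
  y <- runif(25, 10, 60)
  p <- y + rnorm(25, 0, 12)
  thr <- median(y)
  m <- classificationMetrics(p, y, threshold = thr)
  ref <- pROC::roc(response = factor(y < thr, levels = c(FALSE, TRUE)),
                   predictor = -p, direction = "<", quiet = TRUE)
  expect_equal(m$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("single-class inputs flag AUC undefined but keep table metrics", {
  m <- classificationMetrics(c(50, 55), c(50, 55), threshold = 38)
  expect_false(m$aucDefined)
  expect_true(is.na(m$auc))
  expect_equal(m$accuracy, 100)
})

test_that("naive baseline predicts the cohort median", {
  same <- naiveBaseline(rep(40, 5), tol = 10)
  expect_equal(same$accuracy, 100)
  expect_equal(same$mae, 0)
  m <- naiveBaseline(c(28, 38, 60), tol = 10)
  expect_equal(m$medianPrediction, 38)
  expect_equal(m$accuracy, 100 * 2 / 3, tolerance = 1e-10)
  expect_equal(m$mae, (10 + 0 + 22) / 3, tolerance = 1e-10)
})

test_that("ROC coordinates span (0,1) sensitivity and nest monotonically", {
  set.seed(17)
  y <- runif(15, 10, 60); p <- y + rnorm(15, 0, 10)
  roc <- rocCoordinates(p, y, threshold = median(y))
  expect_equal(roc$sensitivity[1L], 1)           # call everything positive
  expect_equal(roc$sensitivity[nrow(roc)], 0)
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
})

test_that("cross-validation predicts every thrombus exactly once, leak-free", {
  coh <- smallCohort()
  rep1 <- runCrossValidation(coh, hp = HyperParams(nEpochs = 2L, seed = 1L),
                             evalConfig = EvalConfig(kFolds = 2L, seed = 5L))
  pred <- reportPredictions(rep1)
  expect_setequal(pred$thrombusId, thrombusData(coh)$thrombusId)
  expect_equal(anyDuplicated(pred$thrombusId), 0L)
  folds <- rep1@folds$assignment
  for (f in seq_along(folds)) {
    inFold <- pred$thrombusId %in% folds[[f]]
    expect_true(all(pred$fold[inFold] == f))
  }
  # subset restricted to the full range equals the full metrics
  ec <- EvalConfig(kFolds = 2L, seed = 5L, subsetRange = c(0, 100))
  rep2 <- runCrossValidation(coh, hp = HyperParams(nEpochs = 2L, seed = 1L),
                             evalConfig = ec)
  expect_equal(rep2@metrics$subset[c("accuracy", "mae")],
               rep2@metrics$thrombusRegression[c("accuracy", "mae")])
})

test_that("fold assignment is shared between original and augmented runs", {
  coh <- smallCohort()
  ec <- EvalConfig(kFolds = 2L, seed = 9L)
  hp <- HyperParams(nEpochs = 1L, seed = 2L)
  a <- runCrossValidation(coh, hp = hp, evalConfig = ec)
  b <- runCrossValidation(coh, hp = hp,
                          augConfig = AugmentConfig(duplicationFactor = 1L,
                                                    seed = 4L),
                          evalConfig = ec)
  expect_identical(a@folds$assignment, b@folds$assignment)
})
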