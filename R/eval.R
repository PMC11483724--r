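## Grouped cross-validation driver and the metric suite.

#' Grouped k-fold split at the thrombus level
#'
#' Randomly partitions thrombus IDs (never slices) into k folds whose sizes
#' differ by at most one, so that no thrombus contributes slices to both
#' the training and test side of any fold. The partition is a function of
#' the seed only.
#'
#' @param cohort a [ThrombusCohort-class].
#' @param k number of folds (2 <= k <= number of thrombi).
#' @param seed integer seed.
#' @return list of k character vectors of thrombus IDs.
#' @export
groupedKFoldSplit <- function(cohort, k, seed) {
  ids <- cohort@thrombi$thrombusId
  n <- length(ids)
  k <- as.integer(k)
  if (k < 2L || k > n)
    stop(sprintf("groupedKFoldSplit: k must be in [2, %d], got %d", n, k))
  perm <- withSeed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(ids[perm], rep(seq_len(k), times = sizes))
}

#' Aggregate slice predictions to a thrombus prediction
#'
#' The thrombus-level RBC prediction is the median of its slice
#' predictions (midpoint of the two central values for even counts).
#'
#' @param slicePredictions numeric vector (>= 1).
#' @return scalar median prediction.
#' @export
aggregateThrombusPrediction <- function(slicePredictions) {
  if (!length(slicePredictions))
    stop("aggregateThrombusPrediction: empty prediction vector")
  median(slicePredictions)
}

#' Regression metric record
#'
#' Accuracy (fraction of predictions within `tol` percentage points of the
#' truth, reported in %), mean absolute error, Pearson r and the
#' least-squares slope of predictions regressed on truths. With zero
#' variance in the truths, r and slope are returned as `NA` and flagged.
#'
#' @param predictions,truths equal-length numeric vectors (>= 1; >= 2 for
#'   r and slope).
#' @param tol accuracy tolerance in percentage points (default 10).
#' @return list: `accuracy` (%), `mae`, `pearsonR`, `slope`,
#'   `correlationDefined`, `n`.
#' @export
regressionMetrics <- function(predictions, truths, tol = 10) {
  n <- length(truths)
  if (length(predictions) != n || n < 1L)
    stop("regressionMetrics: need equal-length vectors of length >= 1")
  err <- abs(predictions - truths)
  accuracy <- 100 * mean(err <= tol)
  mae <- mean(err)
  defined <- n >= 2L && sd(truths) > 0 && sd(predictions) > 0
  slopeDefined <- n >= 2L && sd(truths) > 0
  list(accuracy = accuracy, mae = mae,
       pearsonR = if (defined) cor(predictions, truths) else NA_real_,
       slope = if (slopeDefined)
         unname(coef(lm(predictions ~ truths))[2L]) else NA_real_,
       correlationDefined = defined, n = n)
}

## Tie-corrected rank (Mann-Whitney) AUC: probability that a random
## positive outranks a random negative, ties counting one half.
rankAuc <- function(scores, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' RBC-rich / RBC-poor classification metrics
#'
#' Thrombi are labeled RBC-poor when the histological truth is strictly
#' below `threshold` and RBC-rich otherwise (values exactly at the
#' threshold are RBC-rich); predicted labels use the same rule on the
#' predictions. Accuracy, sensitivity and specificity come from the
#' confusion table with `positiveClass` as the positive class; the AUC is
#' the tie-corrected rank (Mann-Whitney) statistic on the continuous
#' score, oriented so that a lower predicted RBC content scores higher for
#' RBC-poor. When only one true class is present the AUC is `NA`.
#'
#' @param predictions,truths equal-length numeric RBC percentages.
#' @param threshold classification threshold in \%.
#' @param positiveClass `"RBC-poor"` (default) or `"RBC-rich"`.
#' @return list: `accuracy`, `sensitivity`, `specificity` (all \%), `auc`,
#'   `aucDefined`, `threshold`, `confusion` (2x2 table), `trueLabel`,
#'   `predictedLabel`.
#' @export
classificationMetrics <- function(predictions, truths, threshold,
                                  positiveClass = "RBC-poor") {
  n <- length(truths)
  if (length(predictions) != n || n < 1L)
    stop("classificationMetrics: need equal-length vectors")
  lab <- function(x) ifelse(x < threshold, "RBC-poor", "RBC-rich")
  trueLab <- lab(truths)
  predLab <- lab(predictions)
  posTrue <- trueLab == positiveClass
  posPred <- predLab == positiveClass
  tp <- sum(posTrue & posPred); fn <- sum(posTrue & !posPred)
  fp <- sum(!posTrue & posPred); tn <- sum(!posTrue & !posPred)
  score <- if (positiveClass == "RBC-poor") -predictions else predictions
  auc <- rankAuc(score, posTrue)
  list(accuracy = 100 * (tp + tn) / n,
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
       auc = auc, aucDefined = !is.na(auc), threshold = threshold,
       confusion = matrix(c(tp, fn, fp, tn), 2L, 2L,
                          dimnames = list(predicted = c("positive", "negative"),
                                          truth = c("positive", "negative"))),
       trueLabel = trueLab, predictedLabel = predLab)
}

#' ROC coordinates for the RBC-poor score
#'
#' Sensitivity/specificity pairs obtained by sweeping the decision
#' threshold over the (negated-prediction) scores.
#'
#' @param predictions,truths numeric RBC percentages.
#' @param threshold truth threshold defining RBC-poor.
#' @return data.frame with columns `scoreCutoff`, `sensitivity`,
#'   `specificity` (fractions in \[0, 1\]).
#' @export
rocCoordinates <- function(predictions, truths, threshold) {
  positive <- truths < threshold
  score <- -predictions
  cuts <- c(-Inf, sort(unique(score)), Inf)
  do.call(rbind, lapply(cuts, function(ct) {
    called <- score >= ct
    data.frame(scoreCutoff = ct,
               sensitivity = if (any(positive))
                 sum(called & positive) / sum(positive) else NA_real_,
               specificity = if (any(!positive))
                 sum(!called & !positive) / sum(!positive) else NA_real_)
  }))
}

#' Naive cohort-median baseline
#'
#' Predicts the cohort-median RBC content for every thrombus and scores
#' the result with [regressionMetrics]; the reference point against which
#' the network's accuracy and absolute error are judged.
#'
#' @param truths numeric RBC percentages (>= 1).
#' @param tol accuracy tolerance in percentage points.
#' @return the [regressionMetrics] record plus `medianPrediction`.
#' @export
naiveBaseline <- function(truths, tol = 10) {
  if (!length(truths)) stop("naiveBaseline: empty truth vector")
  m <- median(truths)
  res <- regressionMetrics(rep(m, length(truths)), truths, tol)
  res$medianPrediction <- m
  res
}

resolveThreshold <- function(evalConfig, truths) {
  if (identical(evalConfig@richPoorThreshold, "cohort-median"))
    median(truths)
  else as.numeric(evalConfig@richPoorThreshold)
}

#' Grouped k-fold cross-validation of the full pipeline
#'
#' For each fold: canvas-standardizes all slices, computes the z-score
#' normalization statistics under the configured scope (`"all"` pools all
#' segmented thrombi, the protocol-faithful default; `"train"` restricts to
#' the training fold), augments the training slices only (when `augConfig`
#' is supplied), trains a fresh network, predicts the held-out slices and
#' aggregates them per thrombus by the median. After all folds the pooled
#' test predictions (every thrombus predicted exactly once) are scored
#' with the full metric suite: slice- and thrombus-level regression
#' metrics, RBC-rich/RBC-poor classification with ROC coordinates, the
#' naive cohort-median baseline, and the metrics restricted to thrombi
#' with truths inside `subsetRange`.
#'
#' Seeding: fold assignment depends only on `evalConfig@seed`; per-fold
#' network initialization, training and augmentation seeds are derived
#' from `hp@seed` and `augConfig@seed` by fixed fold offsets, so the fold
#' split is identical between augmented and original runs of the same
#' configuration.
#'
#' @param cohort a raw [ThrombusCohort-class] (slices on any canvas).
#' @param arch an [ArchConfig-class].
#' @param hp a [HyperParams-class].
#' @param augConfig an [AugmentConfig-class], or `NULL` for the original
#'   (non-augmented) pipeline.
#' @param evalConfig an [EvalConfig-class].
#' @param verbose print per-fold progress.
#' @return An [EvaluationReport-class].
#' @export
runCrossValidation <- function(cohort, arch = ArchConfig(),
                               hp = HyperParams(), augConfig = NULL,
                               evalConfig = EvalConfig(), verbose = FALSE) {
  validObject(cohort); validObject(arch); validObject(hp)
  validObject(evalConfig)
  if (!is.null(augConfig)) validObject(augConfig)
  t0 <- proc.time()[["elapsed"]]
  folds <- groupedKFoldSplit(cohort, evalConfig@kFolds, evalConfig@seed)
  thr <- cohort@thrombi
  truthOf <- structure(thr$rbcPercent, names = thr$thrombusId)

  height <- arch@inputShape[1L]; width <- arch@inputShape[2L]
  std <- lapply(cohort@slices, standardizeCanvas, height = height,
                width = width)
  sliceIds <- vapply(std, function(s) s@thrombusId, "")
  sliceTruth <- unname(truthOf[sliceIds])
  statsAll <- if (evalConfig@normScope == "all") computeNormStats(std)

  slicePred <- data.frame(thrombusId = character(), sliceIndex = integer(),
                          truth = numeric(), prediction = numeric(),
                          fold = integer())
  thrombusPred <- data.frame(thrombusId = character(), truth = numeric(),
                             prediction = numeric(), fold = integer())
  foldDetails <- vector("list", length(folds))

  for (f in seq_along(folds)) {
    testIds <- folds[[f]]
    testMask <- sliceIds %in% testIds
    trainSet <- std[!testMask]
    trainRbc <- sliceTruth[!testMask]
    if (length(intersect(unique(sliceIds[!testMask]), testIds)))
      stop(sprintf("fold %d: thrombus leakage between train and test", f))
    stats <- if (evalConfig@normScope == "all") statsAll
             else computeNormStats(trainSet)
    trainNorm <- lapply(trainSet, normalizeSlice, stats = stats)
    testNorm <- lapply(std[testMask], normalizeSlice, stats = stats)
    nAug <- length(trainNorm)
    if (!is.null(augConfig)) {
      ac <- augConfig
      ac@seed <- deriveSeed(augConfig@seed, 10L * f)
      aug <- augmentTrainingSet(trainNorm, trainRbc, ac)
      trainNorm <- aug$slices
      trainRbc <- aug$rbc
      nAug <- length(trainNorm)
    }
    hpF <- hp
    hpF@seed <- deriveSeed(hp@seed, 20L * f + 1L)
    net <- buildNetwork(arch, seed = deriveSeed(hp@seed, 20L * f))
    net <- tryCatch(trainNetwork(net, trainNorm, trainRbc, hpF),
                    error = function(e)
                      stop(sprintf("fold %d failed: %s", f,
                                   conditionMessage(e))))
    preds <- predictSlices(net, testNorm)
    testSliceIds <- sliceIds[testMask]
    slicePred <- rbind(slicePred, data.frame(
      thrombusId = testSliceIds,
      sliceIndex = vapply(std[testMask], function(s) s@sliceIndex, 0L),
      truth = sliceTruth[testMask], prediction = preds, fold = f))
    agg <- tapply(preds, testSliceIds, aggregateThrombusPrediction)
    thrombusPred <- rbind(thrombusPred, data.frame(
      thrombusId = names(agg), truth = unname(truthOf[names(agg)]),
      prediction = as.numeric(agg), fold = f))
    foldDetails[[f]] <- list(testIds = testIds, nTrain = nAug,
                             finalLoss = tail(net@lossHistory, 1L))
    if (verbose)
      message(sprintf("fold %d/%d: %d training slices, %d test thrombi",
                      f, length(folds), nAug, length(testIds)))
  }

  tol <- evalConfig@accuracyTol
  threshold <- resolveThreshold(evalConfig, thr$rbcPercent)
  cls <- classificationMetrics(thrombusPred$prediction, thrombusPred$truth,
                               threshold, evalConfig@positiveClass)
  inSubset <- thrombusPred$truth >= evalConfig@subsetRange[1L] &
    thrombusPred$truth <= evalConfig@subsetRange[2L]
  metrics <- list(
    sliceRegression = regressionMetrics(slicePred$prediction,
                                        slicePred$truth, tol),
    thrombusRegression = regressionMetrics(thrombusPred$prediction,
                                           thrombusPred$truth, tol),
    classification = cls,
    naive = naiveBaseline(thr$rbcPercent, tol),
    subset = if (any(inSubset))
      regressionMetrics(thrombusPred$prediction[inSubset],
                        thrombusPred$truth[inSubset], tol))
  thrombusPred$trueLabel <- cls$trueLabel
  thrombusPred$predictedLabel <- cls$predictedLabel
  roc <- rocCoordinates(thrombusPred$prediction, thrombusPred$truth,
                        threshold)
  new("EvaluationReport",
      predictions = thrombusPred, slicePredictions = slicePred,
      metrics = metrics, roc = roc,
      folds = list(assignment = folds, details = foldDetails),
      provenance = list(
        evalSeed = evalConfig@seed, hpSeed = hp@seed,
        augSeed = if (!is.null(augConfig)) augConfig@seed,
        augmented = !is.null(augConfig),
        threshold = threshold, normScope = evalConfig@normScope,
        configHash = fnv1a64(list(
          arch = configToList(arch), hp = configToList(hp),
          aug = if (!is.null(augConfig)) configToList(augConfig),
          eval = configToList(evalConfig))),
        elapsedSec = proc.time()[["elapsed"]] - t0))
}
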