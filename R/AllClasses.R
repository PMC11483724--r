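#' @import methods
#' @importFrom stats median quantile rnorm runif rbeta rlnorm rpois sd optim
#'   cor coef lm
#' @importFrom utils read.csv write.csv head tail
NULL

#' Configuration of the synthetic thrombus cohort generator
#'
#' Holds every knob of the synthetic ex vivo thrombus cohort: cohort size,
#' per-thrombus slice allocation, the quantile anchors of the histological
#' RBC-content distribution, the latent oxygenation confounder spread, the
#' texture correlation length, per-channel tissue calibration values, the
#' late echo time used to derive the GRE magnitude channel, noise levels,
#' canvas size and the seed. The default values are calibrated so that a
#' large generated cohort reproduces the summary statistics of the ex vivo
#' thrombus cohort the generator emulates (median RBC 38%, median thrombus
#' R2* 39 s^-1, median QSM 0.017 ppm, near-zero correlation between mean
#' imaging values and RBC content).
#'
#' @slot nThrombi number of thrombi.
#' @slot totalSlices total number of MR slices over the whole cohort.
#' @slot sliceAllocation `"fixed-list"` (deterministic near-even allocation)
#'   or `"poisson-adjusted"` (Poisson draws adjusted to the exact total).
#' @slot rbcQuantiles numeric(5): min, Q1, median, Q3, max anchors of the
#'   RBC\% distribution, strictly increasing within \[0, 100\].
#' @slot oxygenationSd log-scale SD of the latent lognormal oxygenation
#'   factor shared by the R2* and QSM patch amplitudes (dimensionless).
#' @slot patchCorrLen correlation length (pixels) of the Gaussian random
#'   field whose threshold defines RBC patches.
#' @slot calibration named numeric: `r2sLow`/`r2sHigh` (s^-1), `qsmLow`/
#'   `qsmHigh` (ppm), `m0` (GRE equilibrium magnitude, a.u.).
#' @slot teLate late echo time in seconds (default 0.031).
#' @slot noiseSd named numeric(3): additive Gaussian noise SD per channel
#'   (`r2star` s^-1, `qsm` ppm, `gre` a.u.).
#' @slot canvas integer(2): generation canvas (height, width) in pixels.
#' @slot seed integer RNG seed.
#' @export
setClass("GeneratorConfig",
  representation(
    nThrombi = "integer", totalSlices = "integer",
    sliceAllocation = "character", rbcQuantiles = "numeric",
    oxygenationSd = "numeric", patchCorrLen = "numeric",
    calibration = "numeric", teLate = "numeric", noiseSd = "numeric",
    canvas = "integer", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (length(object@nThrombi) != 1L || is.na(object@nThrombi) ||
      object@nThrombi < 1L)
    msg <- c(msg, "nThrombi: must be a single integer >= 1")
  if (length(object@totalSlices) != 1L || is.na(object@totalSlices) ||
      object@totalSlices < object@nThrombi)
    msg <- c(msg, "totalSlices: must be >= nThrombi")
  if (!object@sliceAllocation %in% c("fixed-list", "poisson-adjusted"))
    msg <- c(msg,
      "sliceAllocation: must be 'fixed-list' or 'poisson-adjusted'")
  q <- object@rbcQuantiles
  if (length(q) != 5L || any(!is.finite(q)) || any(diff(q) <= 0) ||
      q[1L] < 0 || q[5L] > 100)
    msg <- c(msg, paste("rbcQuantiles: need 5 strictly increasing anchors",
                        "(min, Q1, median, Q3, max) within [0, 100]"))
  if (object@oxygenationSd < 0)
    msg <- c(msg, "oxygenationSd: must be >= 0")
  if (object@patchCorrLen < 1)
    msg <- c(msg, "patchCorrLen: must be >= 1 pixel")
  need <- c("r2sLow", "r2sHigh", "qsmLow", "qsmHigh", "m0")
  if (!all(need %in% names(object@calibration)))
    msg <- c(msg, paste("calibration: must name", paste(need, collapse = ", ")))
  if (object@teLate <= 0)
    msg <- c(msg, "teLate: must be > 0 seconds")
  if (length(object@noiseSd) != 3L || any(object@noiseSd < 0))
    msg <- c(msg, "noiseSd: need 3 nonnegative per-channel values")
  if (length(object@canvas) != 2L || any(object@canvas < 8L))
    msg <- c(msg, "canvas: need (height, width) >= 8 pixels")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' A single 3-channel masked MR thrombus slice
#'
#' One 2-D slice of a thrombus as fed through the pipeline: three real-valued
#' channels (R2* in s^-1, QSM in ppm, late-echo GRE magnitude in arbitrary
#' units) on a common pixel grid, a binary in-thrombus mask, and provenance
#' (thrombus ID, slice index, optional augmentation-instance ID).
#'
#' @slot thrombusId character thrombus identifier.
#' @slot sliceIndex integer slice index within the thrombus (1-based).
#' @slot channels numeric array (height, width, 3), third dimension named
#'   `r2star`, `qsm`, `gre`.
#' @slot mask numeric matrix of 0/1 with the channels' spatial dimensions.
#' @slot augmentId character: `""` for an original slice, otherwise a tag
#'   identifying the augmentation copy.
#' @export
setClass("SliceImage",
  representation(thrombusId = "character", sliceIndex = "integer",
                 channels = "array", mask = "matrix",
                 augmentId = "character"),
  prototype(augmentId = ""))

setValidity("SliceImage", function(object) {
  d <- dim(object@channels)
  msg <- character()
  if (length(d) != 3L || d[3L] != 3L)
    msg <- c(msg, "channels: must be a (height, width, 3) array")
  else if (!identical(dim(object@mask), d[1:2]))
    msg <- c(msg, "mask: dimensions must match the channel grid")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask: must be binary (0/1)")
  if (sum(object@mask) < 1)
    msg <- c(msg, "mask: needs at least one foreground pixel")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' A synthetic (or loaded) thrombus cohort
#'
#' The central data container: a thrombus-level table (one row per thrombus
#' with its histological ground-truth RBC percentage and latent diagnostics)
#' plus the list of all [SliceImage] objects, and the generating
#' configuration when the cohort is synthetic.
#'
#' @slot thrombi data.frame with columns `thrombusId`, `rbcPercent`,
#'   `oxygenation`, `nSlices`.
#' @slot slices list of [SliceImage].
#' @slot config the [GeneratorConfig] used, or `NULL` for loaded cohorts.
#' @slot metadata free-form provenance list (seed, creation call, ...).
#' @export
setClass("ThrombusCohort",
  representation(thrombi = "data.frame", slices = "list",
                 config = "ANY", metadata = "list"),
  prototype(metadata = list()))

setValidity("ThrombusCohort", function(object) {
  msg <- character()
  need <- c("thrombusId", "rbcPercent", "oxygenation", "nSlices")
  if (!all(need %in% names(object@thrombi)))
    msg <- c(msg, paste("thrombi: must have columns",
                        paste(need, collapse = ", ")))
  if (nrow(object@thrombi) < 1L)
    msg <- c(msg, "thrombi: cohort must contain at least one thrombus")
  if (anyDuplicated(object@thrombi$thrombusId))
    msg <- c(msg, "thrombi: thrombusId must be unique")
  if (!all(vapply(object@slices, is, TRUE, class2 = "SliceImage")))
    msg <- c(msg, "slices: all elements must be SliceImage objects")
  sid <- vapply(object@slices, function(s) s@thrombusId, "")
  if (length(sid) && !all(sid %in% object@thrombi$thrombusId))
    msg <- c(msg, "slices: every slice must belong to a listed thrombus")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Pooled per-channel z-score normalization statistics
#'
#' Per-channel mean and population standard deviation computed over the
#' pooled in-mask pixels of a stated slice set, with the contributing
#' thrombus IDs recorded for provenance.
#'
#' @slot mean numeric(3) per-channel pooled mean.
#' @slot sd numeric(3) per-channel pooled population SD (all > 0).
#' @slot thrombusIds character: thrombi whose slices contributed.
#' @slot nPixels integer: pooled in-mask pixel count.
#' @export
setClass("NormalizationStats",
  representation(mean = "numeric", sd = "numeric",
                 thrombusIds = "character", nPixels = "integer"))

setValidity("NormalizationStats", function(object) {
  msg <- character()
  if (length(object@mean) != 3L || length(object@sd) != 3L)
    msg <- c(msg, "mean/sd: need exactly 3 per-channel values")
  if (any(!is.finite(object@sd)) || any(object@sd <= 0))
    msg <- c(msg, "sd: all per-channel standard deviations must be > 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Training-set augmentation configuration
#'
#' Parameters of the three-component augmentation scheme: input sampling
#' equalization (RBC-content bins), whole-set duplication, and random
#' geometric transformation (rotation, integer translation, reflection,
#' isotropic scaling, shearing) applied once per duplicated slice.
#'
#' @slot binWidth RBC\% bin width for sampling equalization (default 5).
#' @slot duplicationFactor whole-set duplication multiple (default 5).
#' @slot rotationRange degrees, default c(-90, 90).
#' @slot translationMax maximum integer translation in pixels per axis
#'   (default 5).
#' @slot reflectAxes subset of c("x", "y"); each listed axis is reflected
#'   independently with probability 0.5.
#' @slot scaleRange isotropic scale factor range, default c(0.7, 1.3).
#' @slot shearRange horizontal shear angle range in degrees, default
#'   c(-30, 50).
#' @slot seed integer RNG seed for the augmentation stream.
#' @export
setClass("AugmentConfig",
  representation(binWidth = "numeric", duplicationFactor = "integer",
                 rotationRange = "numeric", translationMax = "integer",
                 reflectAxes = "character", scaleRange = "numeric",
                 shearRange = "numeric", seed = "integer"))

setValidity("AugmentConfig", function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "binWidth: must be > 0")
  if (object@duplicationFactor < 1L)
    msg <- c(msg, "duplicationFactor: must be >= 1")
  ord <- function(r) length(r) == 2L && r[1L] <= r[2L]
  if (!ord(object@rotationRange))
    msg <- c(msg, "rotationRange: need ordered (low, high)")
  if (!ord(object@scaleRange) || any(object@scaleRange <= 0))
    msg <- c(msg, "scaleRange: need ordered positive (low, high)")
  if (!ord(object@shearRange))
    msg <- c(msg, "shearRange: need ordered (low, high)")
  if (object@translationMax < 0L)
    msg <- c(msg, "translationMax: must be >= 0")
  if (!all(object@reflectAxes %in% c("x", "y")))
    msg <- c(msg, "reflectAxes: must be a subset of c('x', 'y')")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' CNN architecture configuration
#'
#' The 3-convolutional-layer regression architecture: three conv layers of
#' 16, 16 and 32 feature channels (3x3 kernels, stride 1, same padding,
#' rectifier activations), 2x2 max pooling after the first two layers,
#' flattening, dropout, and a single linear regression output.
#'
#' @slot convChannels integer(3), default c(16, 16, 32).
#' @slot kernelSize odd kernel size in pixels, default 3.
#' @slot poolAfter indices of conv layers followed by 2x2 max pooling,
#'   default c(1, 2).
#' @slot inputShape integer(3) (height, width, channels), default
#'   c(49, 56, 3).
#' @export
setClass("ArchConfig",
  representation(convChannels = "integer", kernelSize = "integer",
                 poolAfter = "integer", inputShape = "integer"))

setValidity("ArchConfig", function(object) {
  msg <- character()
  if (length(object@convChannels) != 3L || any(object@convChannels < 1L))
    msg <- c(msg, "convChannels: exactly 3 positive channel counts required")
  if (object@kernelSize < 1L || object@kernelSize %% 2L == 0L)
    msg <- c(msg, "kernelSize: must be a positive odd integer")
  if (!all(object@poolAfter %in% 1:3))
    msg <- c(msg, "poolAfter: indices must be within 1..3")
  if (length(object@inputShape) != 3L || any(object@inputShape < 1L))
    msg <- c(msg, "inputShape: need (height, width, channels)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Training hyperparameters
#'
#' Mini-batch Adam training settings: batch size, learning rate, number of
#' epochs, L2 regularization strength lambda (applied to weights only, not
#' biases), dropout rate before the regression head, and the seed driving
#' weight initialization, shuffling and dropout.
#'
#' @slot batchSize integer mini-batch size.
#' @slot learningRate positive Adam step size.
#' @slot nEpochs integer number of passes over the training set (0 allowed:
#'   no training).
#' @slot l2Lambda nonnegative L2 penalty coefficient on weights.
#' @slot dropoutRate dropout probability in \[0, 1).
#' @slot seed integer RNG seed.
#' @export
setClass("HyperParams",
  representation(batchSize = "integer", learningRate = "numeric",
                 nEpochs = "integer", l2Lambda = "numeric",
                 dropoutRate = "numeric", seed = "integer"))

setValidity("HyperParams", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize: must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate: must be > 0")
  if (object@nEpochs < 0L) msg <- c(msg, "nEpochs: must be >= 0")
  if (object@l2Lambda < 0) msg <- c(msg, "l2Lambda: must be >= 0")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate: must be in [0, 1)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' The 3-layer CNN regressor
#'
#' Parameter container for the convolutional RBC-content regressor. Slots
#' hold the architecture, the parameter list (conv kernels as
#' (kernel^2 * inChannels) x outChannels matrices, the dense head, biases),
#' whether the network has been trained, and the per-epoch training loss
#' history.
#'
#' @slot arch the [ArchConfig].
#' @slot params named list of parameter matrices/vectors.
#' @slot trained logical.
#' @slot lossHistory numeric per-epoch mean training loss.
#' @export
setClass("ThrombusNet",
  representation(arch = "ArchConfig", params = "list", trained = "logical",
                 lossHistory = "numeric"),
  prototype(trained = FALSE, lossHistory = numeric()))

#' Cross-validation / evaluation configuration
#'
#' Settings of the grouped k-fold evaluation protocol: fold count, the
#' regression accuracy tolerance in percentage points, the RBC-rich /
#' RBC-poor classification threshold (`"cohort-median"` or an explicit
#' percentage), the restricted RBC range for the subset analysis, the
#' normalization scope, and the fold-assignment seed.
#'
#' @slot kFolds integer, default 8.
#' @slot accuracyTol percentage points, default 10.
#' @slot richPoorThreshold `"cohort-median"` or a numeric string giving the
#'   explicit threshold in \%.
#' @slot subsetRange ordered numeric(2) RBC\% interval, default c(20, 45).
#' @slot positiveClass class treated as positive for sensitivity and AUC,
#'   default `"RBC-poor"`.
#' @slot normScope `"all"` (pooled statistics from all segmented thrombi,
#'   the protocol-faithful default) or `"train"` (leakage-free variant using
#'   the training fold only).
#' @slot seed integer seed for the fold assignment.
#' @export
setClass("EvalConfig",
  representation(kFolds = "integer", accuracyTol = "numeric",
                 richPoorThreshold = "character", subsetRange = "numeric",
                 positiveClass = "character", normScope = "character",
                 seed = "integer"))

setValidity("EvalConfig", function(object) {
  msg <- character()
  if (object@kFolds < 2L) msg <- c(msg, "kFolds: must be >= 2")
  if (object@accuracyTol <= 0) msg <- c(msg, "accuracyTol: must be > 0")
  thr <- object@richPoorThreshold
  if (!identical(thr, "cohort-median") &&
      is.na(suppressWarnings(as.numeric(thr))))
    msg <- c(msg,
      "richPoorThreshold: must be 'cohort-median' or a numeric value")
  if (length(object@subsetRange) != 2L ||
      object@subsetRange[1L] > object@subsetRange[2L])
    msg <- c(msg, "subsetRange: need ordered (low, high)")
  if (!object@positiveClass %in% c("RBC-poor", "RBC-rich"))
    msg <- c(msg, "positiveClass: must be 'RBC-poor' or 'RBC-rich'")
  if (!object@normScope %in% c("all", "train"))
    msg <- c(msg, "normScope: must be 'all' or 'train'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Cross-validation evaluation report
#'
#' Full result of one grouped k-fold cross-validation run: pooled per-slice
#' and per-thrombus regression metrics, RBC-rich/RBC-poor classification
#' metrics with ROC coordinates, the naive cohort-median baseline, the
#' subset-restricted metrics, per-fold details, the per-thrombus prediction
#' table and complete provenance (seeds, fold assignment, config hash).
#'
#' @slot predictions data.frame: one row per thrombus (id, truth,
#'   prediction, fold, true/predicted class labels).
#' @slot slicePredictions data.frame: one row per test slice.
#' @slot metrics named list of pooled metric records (`sliceRegression`,
#'   `thrombusRegression`, `classification`, `naive`, `subset`).
#' @slot roc data.frame of ROC coordinates (threshold, sensitivity,
#'   specificity).
#' @slot folds list: per-fold thrombus IDs and per-fold metrics.
#' @slot provenance list: seeds, config hash, timing.
#' @export
setClass("EvaluationReport",
  representation(predictions = "data.frame", slicePredictions = "data.frame",
                 metrics = "list", roc = "data.frame", folds = "list",
                 provenance = "list"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  need <- c("thrombusId", "truth", "prediction", "fold")
  if (!all(need %in% names(object@predictions)))
    msg <- c(msg, paste("predictions: must have columns",
                        paste(need, collapse = ", ")))
  if (anyDuplicated(object@predictions$thrombusId))
    msg <- c(msg, "predictions: each thrombus must be predicted exactly once")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Full pipeline run configuration
#'
#' Nests every stage configuration plus a run label, output directory and a
#' single global seed from which all module seeds are derived
#' deterministically. Serializes losslessly to and from YAML; unknown YAML
#' keys are rejected.
#'
#' @slot generator [GeneratorConfig].
#' @slot augment [AugmentConfig].
#' @slot arch [ArchConfig].
#' @slot hyper [HyperParams].
#' @slot eval [EvalConfig].
#' @slot label run label.
#' @slot outDir output directory (`""` = return objects only).
#' @slot pipelines subset of c("original", "augmented") to run.
#' @slot seed global integer seed.
#' @export
setClass("RunConfig",
  representation(generator = "GeneratorConfig", augment = "AugmentConfig",
                 arch = "ArchConfig", hyper = "HyperParams",
                 eval = "EvalConfig", label = "character",
                 outDir = "character", pipelines = "character",
                 seed = "integer"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!length(object@pipelines) ||
      !all(object@pipelines %in% c("original", "augmented")))
    msg <- c(msg,
      "pipelines: must be a non-empty subset of c('original', 'augmented')")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
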