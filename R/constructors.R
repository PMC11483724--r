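## User-facing constructors with calibrated defaults, plus small internal
## utilities shared across modules (seed derivation, RNG scoping, hashing).

#' @describeIn GeneratorConfig-class Constructor with calibrated defaults.
#'   `preset = "exvivo"` selects the emulated ex vivo cohort layout (48 thrombi, 188 slices).
#' @param preset `"exvivo"` for the 48-thrombus/188-slice layout, `"custom"`
#'   to take sizes from the arguments.
#' @param nThrombi,totalSlices cohort size (ignored under `preset="exvivo"`).
#' @param sliceAllocation `"fixed-list"` or `"poisson-adjusted"`.
#' @param rbcQuantiles numeric(5) RBC\% anchors (min, Q1, median, Q3, max).
#' @param oxygenationSd log-scale SD of the latent oxygenation factor.
#' @param patchCorrLen texture correlation length in pixels.
#' @param calibration named numeric of channel tissue values (see slots).
#' @param teLate late echo time in seconds.
#' @param noiseSd named numeric(3) of per-channel noise SDs.
#' @param canvas integer(2) canvas (height, width).
#' @param seed integer seed.
#' @export
GeneratorConfig <- function(preset = c("custom", "exvivo"),
                            nThrombi = 48L, totalSlices = 188L,
                            sliceAllocation = "fixed-list",
                            rbcQuantiles = c(12, 30, 38, 49, 61),
                            oxygenationSd = 1.2,
                            patchCorrLen = 3,
                            calibration = c(r2sLow = 15, r2sHigh = 84,
                                            qsmLow = -0.03, qsmHigh = 0.100,
                                            m0 = 100),
                            teLate = 0.031,
                            noiseSd = c(r2star = 3, qsm = 0.01, gre = 2),
                            canvas = c(49L, 56L),
                            seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "exvivo") {
    nThrombi <- 48L
    totalSlices <- 188L
    sliceAllocation <- "fixed-list"
  }
  new("GeneratorConfig",
      nThrombi = as.integer(nThrombi), totalSlices = as.integer(totalSlices),
      sliceAllocation = sliceAllocation, rbcQuantiles = as.numeric(rbcQuantiles),
      oxygenationSd = as.numeric(oxygenationSd),
      patchCorrLen = as.numeric(patchCorrLen),
      calibration = calibration, teLate = as.numeric(teLate),
      noiseSd = noiseSd, canvas = as.integer(canvas),
      seed = as.integer(seed))
}

#' @describeIn AugmentConfig-class Constructor with the reference transform
#'   ranges as defaults.
#' @param binWidth,duplicationFactor,rotationRange,translationMax
#'   see the class slots.
#' @param reflectAxes,scaleRange,shearRange,seed see the class slots.
#' @export
AugmentConfig <- function(binWidth = 5, duplicationFactor = 5L,
                          rotationRange = c(-90, 90), translationMax = 5L,
                          reflectAxes = c("x", "y"),
                          scaleRange = c(0.7, 1.3), shearRange = c(-30, 50),
                          seed = 1L) {
  new("AugmentConfig", binWidth = as.numeric(binWidth),
      duplicationFactor = as.integer(duplicationFactor),
      rotationRange = as.numeric(rotationRange),
      translationMax = as.integer(translationMax),
      reflectAxes = as.character(reflectAxes),
      scaleRange = as.numeric(scaleRange),
      shearRange = as.numeric(shearRange), seed = as.integer(seed))
}

#' An AugmentConfig whose random transform collapses to the identity
#'
#' Convenience preset: equalization and duplication left configurable but
#' rotation, translation, reflection, scaling and shearing all collapsed so
#' the geometric transform is the exact identity map. Used to verify that
#' the augmented pipeline degenerates to the original one.
#'
#' @param binWidth,duplicationFactor,seed passed through.
#' @return An [AugmentConfig-class].
#' @export
identityAugmentConfig <- function(binWidth = 5, duplicationFactor = 1L,
                                  seed = 1L) {
  AugmentConfig(binWidth = binWidth, duplicationFactor = duplicationFactor,
                rotationRange = c(0, 0), translationMax = 0L,
                reflectAxes = character(), scaleRange = c(1, 1),
                shearRange = c(0, 0), seed = seed)
}

#' @describeIn ArchConfig-class Constructor; defaults give the 3-layer
#'   16/16/32 architecture on 49 x 56 x 3 inputs.
#' @param convChannels,kernelSize,poolAfter,inputShape see the class slots.
#' @export
ArchConfig <- function(convChannels = c(16L, 16L, 32L), kernelSize = 3L,
                       poolAfter = c(1L, 2L),
                       inputShape = c(49L, 56L, 3L)) {
  new("ArchConfig", convChannels = as.integer(convChannels),
      kernelSize = as.integer(kernelSize), poolAfter = as.integer(poolAfter),
      inputShape = as.integer(inputShape))
}

#' @describeIn HyperParams-class Constructor with the package's default
#'   Adam regime.
#' @param batchSize,learningRate,nEpochs,l2Lambda,dropoutRate,seed see the
#'   class slots.
#' @export
HyperParams <- function(batchSize = 32L, learningRate = 3e-3,
                        nEpochs = 60L, l2Lambda = 1e-4, dropoutRate = 0.2,
                        seed = 1L) {
  new("HyperParams", batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), nEpochs = as.integer(nEpochs),
      l2Lambda = as.numeric(l2Lambda), dropoutRate = as.numeric(dropoutRate),
      seed = as.integer(seed))
}

#' @describeIn EvalConfig-class Constructor with the 8-fold / 10-point /
#'   cohort-median defaults.
#' @param kFolds,accuracyTol,richPoorThreshold,subsetRange see class slots.
#' @param positiveClass,normScope,seed see the class slots.
#' @export
EvalConfig <- function(kFolds = 8L, accuracyTol = 10,
                       richPoorThreshold = "cohort-median",
                       subsetRange = c(20, 45), positiveClass = "RBC-poor",
                       normScope = "all", seed = 1L) {
  new("EvalConfig", kFolds = as.integer(kFolds),
      accuracyTol = as.numeric(accuracyTol),
      richPoorThreshold = as.character(richPoorThreshold),
      subsetRange = as.numeric(subsetRange),
      positiveClass = positiveClass, normScope = normScope,
      seed = as.integer(seed))
}

#' @describeIn RunConfig-class Constructor nesting all stage configurations.
#' @param generator,augment,arch,hyper,eval stage configurations.
#' @param label,outDir,pipelines,seed see the class slots.
#' @export
RunConfig <- function(generator = GeneratorConfig("exvivo"),
                      augment = AugmentConfig(),
                      arch = ArchConfig(), hyper = HyperParams(),
                      eval = EvalConfig(), label = "run",
                      outDir = "", pipelines = c("original", "augmented"),
                      seed = 1L) {
  cfg <- new("RunConfig", generator = generator, augment = augment,
             arch = arch, hyper = hyper, eval = eval, label = label,
             outDir = outDir, pipelines = pipelines, seed = as.integer(seed))
  deriveModuleSeeds(cfg)
}

## Module seeds are fixed offsets of the global seed so one integer
## reproduces the whole run; kept below 2^31 - 1.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483629)
}

deriveModuleSeeds <- function(cfg) {
  s <- cfg@seed
  cfg@generator@seed <- deriveSeed(s, 1L)
  cfg@augment@seed <- deriveSeed(s, 2L)
  cfg@hyper@seed <- deriveSeed(s, 3L)
  cfg@eval@seed <- deriveSeed(s, 4L)
  cfg
}

## Evaluate expr under a private, fully specified RNG state; the caller's
## stream is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

## Two independent 32-bit FNV-1a streams over a canonical serialization,
## concatenated to 16 hex chars. Arithmetic kept exact in doubles by
## splitting the 32-bit state into 16-bit limbs before multiplying.
fnv1a64 <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  mul32 <- function(a, b) { # a < 2^32, b < 2^25
    lo <- (a %% 65536) * b
    hi <- (floor(a / 65536) %% 65536) * b
    (lo + (hi %% 65536) * 65536) %% 4294967296
  }
  step <- function(h, b) {
    q <- floor(h / 256) * 256
    mul32(q + bitwXor(as.integer(h %% 256), b), 16777619)
  }
  h1 <- 2166136261; h2 <- 0x811c9dc4
  for (b in bytes) { h1 <- step(h1, b); h2 <- step(h2, b) }
  hex32 <- function(h) sprintf("%04x%04x", as.integer(h / 65536),
                               as.integer(h %% 65536))
  paste0(hex32(h1), hex32(h2))
}

#' Provenance hash of a configuration object
#'
#' Deterministic 64-bit FNV-1a hash of the canonical YAML serialization of
#' a configuration; embedded in every report so results can be traced to
#' their exact configuration.
#'
#' @param config any of the package's configuration objects.
#' @return A 16-character hex string.
#' @export
configHash <- function(config) {
  fnv1a64(configToList(config))
}
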