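## Generics, accessors and show methods.

#' Number of thrombi in a cohort
#' @param object a [ThrombusCohort-class].
#' @return integer count.
#' @export
setGeneric("nThrombi", function(object) standardGeneric("nThrombi"))

#' @rdname nThrombi
#' @export
setMethod("nThrombi", "ThrombusCohort",
          function(object) nrow(object@thrombi))

#' Number of slices in a cohort
#' @param object a [ThrombusCohort-class].
#' @return integer count.
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))

#' @rdname nSlices
#' @export
setMethod("nSlices", "ThrombusCohort",
          function(object) length(object@slices))

#' Slice list of a cohort
#' @param object a [ThrombusCohort-class].
#' @return list of [SliceImage-class].
#' @export
setGeneric("slices", function(object) standardGeneric("slices"))

#' @rdname slices
#' @export
setMethod("slices", "ThrombusCohort", function(object) object@slices)

#' Thrombus-level ground-truth table
#' @param object a [ThrombusCohort-class].
#' @return data.frame with one row per thrombus.
#' @export
setGeneric("thrombusData", function(object) standardGeneric("thrombusData"))

#' @rdname thrombusData
#' @export
setMethod("thrombusData", "ThrombusCohort", function(object) object@thrombi)

#' Ground-truth RBC percentages of a cohort
#' @param object a [ThrombusCohort-class].
#' @return named numeric vector (names = thrombus IDs).
#' @export
setGeneric("rbcPercent", function(object) standardGeneric("rbcPercent"))

#' @rdname rbcPercent
#' @export
setMethod("rbcPercent", "ThrombusCohort", function(object)
  structure(object@thrombi$rbcPercent, names = object@thrombi$thrombusId))

#' Channel array of a slice
#' @param object a [SliceImage-class].
#' @return numeric array (height, width, 3).
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))

#' @rdname channels
#' @export
setMethod("channels", "SliceImage", function(object) object@channels)

#' Binary mask of a slice
#' @param object a [SliceImage-class].
#' @return 0/1 numeric matrix.
#' @export
setGeneric("sliceMask", function(object) standardGeneric("sliceMask"))

#' @rdname sliceMask
#' @export
setMethod("sliceMask", "SliceImage", function(object) object@mask)

#' Pooled evaluation metrics of a report
#' @param object an [EvaluationReport-class].
#' @return named list of metric records.
#' @export
setGeneric("reportMetrics", function(object) standardGeneric("reportMetrics"))

#' @rdname reportMetrics
#' @export
setMethod("reportMetrics", "EvaluationReport", function(object) object@metrics)

#' Per-thrombus prediction table of a report
#' @param object an [EvaluationReport-class].
#' @return data.frame, one row per thrombus.
#' @export
setGeneric("reportPredictions",
           function(object) standardGeneric("reportPredictions"))

#' @rdname reportPredictions
#' @export
setMethod("reportPredictions", "EvaluationReport",
          function(object) object@predictions)

setMethod("show", "ThrombusCohort", function(object) {
  cat("ThrombusCohort:", nrow(object@thrombi), "thrombi,",
      length(object@slices), "slices\n")
  cat("  RBC% median:", signif(median(object@thrombi$rbcPercent), 3),
      " range:", signif(min(object@thrombi$rbcPercent), 3), "-",
      signif(max(object@thrombi$rbcPercent), 3), "\n")
  if (!is.null(object@metadata$configHash))
    cat("  config hash:", object@metadata$configHash, "\n")
})

setMethod("show", "SliceImage", function(object) {
  d <- dim(object@channels)
  cat("SliceImage", sprintf("%s/%d", object@thrombusId, object@sliceIndex),
      sprintf("(%d x %d x %d,", d[1L], d[2L], d[3L]),
      sum(object@mask), "mask px)\n")
})

setMethod("show", "NormalizationStats", function(object) {
  cat("NormalizationStats over", length(object@thrombusIds), "thrombi,",
      object@nPixels, "pooled in-mask pixels\n")
  m <- rbind(mean = object@mean, sd = object@sd)
  colnames(m) <- c("r2star", "qsm", "gre")
  print(signif(m, 4))
})

setMethod("show", "ThrombusNet", function(object) {
  np <- sum(vapply(object@params, length, 0L))
  cat("ThrombusNet: conv", paste(object@arch@convChannels, collapse = "/"),
      "on", paste(object@arch@inputShape, collapse = "x"), "inputs;",
      np, "parameters;", if (object@trained) "trained" else "untrained", "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", nrow(object@predictions), "thrombi,",
      length(object@folds$assignment), "folds\n")
  tm <- object@metrics$thrombusRegression
  cl <- object@metrics$classification
  if (!is.null(tm))
    cat(sprintf("  thrombus-level: accuracy %.1f%%  MAE %.2f  r %.2f  slope %.2f\n",
                tm$accuracy, tm$mae, tm$pearsonR, tm$slope))
  if (!is.null(cl))
    cat(sprintf("  RBC-poor classification: accuracy %.1f%%  AUC %.3f\n",
                cl$accuracy, cl$auc))
})
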