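## Configuration schema (YAML), cohort/report I/O, and the end-to-end
## pipeline driver.

## ---- config <-> list -------------------------------------------------

configToList <- function(config) {
  if (is.null(config)) return(NULL)
  out <- list()
  for (nm in methods::slotNames(class(config))) {
    v <- methods::slot(config, nm)
    out[[nm]] <- if (isS4(v)) configToList(v)
    else if (is.numeric(v) && !is.null(names(v))) as.list(v)
    else v
  }
  out
}

## Override the slots of a config object from a named list, rejecting
## unknown keys with the offending location.
applyOverrides <- function(config, values, where) {
  if (is.null(values)) return(config)
  if (!is.list(values))
    stop(sprintf("config error at '%s': expected a mapping", where))
  legal <- methods::slotNames(class(config))
  for (nm in names(values)) {
    if (!nm %in% legal)
      stop(sprintf("config error: unknown field '%s' in '%s'", nm, where))
    cur <- methods::slot(config, nm)
    v <- values[[nm]]
    if (is.list(v) && !is.null(names(v)) && is.numeric(cur))
      v <- unlist(v)
    if (is.integer(cur)) v <- as.integer(v)
    if (is.numeric(cur) && !is.null(names(cur)) && is.null(names(v)))
      names(v) <- names(cur)
    if (is.character(cur)) v <- as.character(v)
    methods::slot(config, nm) <- v
  }
  validObject(config)
  config
}

#' Load a pipeline configuration from YAML
#'
#' Reads a (possibly partial) YAML file into a [RunConfig-class]. Missing
#' fields take the documented defaults; unknown keys raise a schema error
#' naming the field and its location. An empty file yields the full
#' default configuration. Module seeds are always (re-)derived from the
#' global seed.
#'
#' @param path YAML file path.
#' @return A validated [RunConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("loadConfig: no such file: ", path)
  values <- yaml::read_yaml(path)
  if (is.null(values)) values <- list()
  sections <- c("generator", "augment", "arch", "hyper", "eval")
  scalars <- c("label", "outDir", "pipelines", "seed")
  unknown <- setdiff(names(values), c(sections, scalars))
  if (length(unknown))
    stop("config error: unknown field '", unknown[1L], "' at top level")
  cfg <- RunConfig()
  for (sec in sections)
    methods::slot(cfg, sec) <- applyOverrides(methods::slot(cfg, sec),
                                              values[[sec]], sec)
  if (!is.null(values$label)) cfg@label <- as.character(values$label)
  if (!is.null(values$outDir)) cfg@outDir <- as.character(values$outDir)
  if (!is.null(values$pipelines))
    cfg@pipelines <- as.character(unlist(values$pipelines))
  if (!is.null(values$seed)) cfg@seed <- as.integer(values$seed)
  validObject(cfg)
  deriveModuleSeeds(cfg)
}

#' Save a pipeline configuration to YAML
#'
#' Lossless counterpart of [loadConfig]: `loadConfig(saveConfig(cfg, f))`
#' reproduces `cfg` exactly.
#'
#' @param config a [RunConfig-class].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  validObject(config)
  out <- list(generator = configToList(config@generator),
              augment = configToList(config@augment),
              arch = configToList(config@arch),
              hyper = configToList(config@hyper),
              eval = configToList(config@eval),
              label = config@label, outDir = config@outDir,
              pipelines = as.list(config@pipelines), seed = config@seed)
  yaml::write_yaml(out, path)
  invisible(path)
}

## ---- cohort I/O ------------------------------------------------------

#' Write a cohort to disk (NIfTI slices + CSV manifest + YAML config)
#'
#' Each slice becomes one 4-volume NIfTI file (volumes: r2star, qsm, gre,
#' mask); the manifest CSV links thrombus IDs, slice indices, files and
#' ground-truth RBC percentages; the generating configuration (when
#' present) is echoed as YAML.
#'
#' @param cohort a [ThrombusCohort-class].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(cohort@slices))
  truthOf <- structure(cohort@thrombi$rbcPercent,
                       names = cohort@thrombi$thrombusId)
  for (i in seq_along(cohort@slices)) {
    s <- cohort@slices[[i]]
    fname <- sprintf("%s_s%02d.nii.gz", s@thrombusId, s@sliceIndex)
    vol <- array(0, c(dim(s@mask), 4L))
    vol[, , 1:3] <- s@channels
    vol[, , 4L] <- s@mask
    RNifti::writeNifti(vol, file.path(dir, fname))
    rows[[i]] <- data.frame(thrombus_id = s@thrombusId,
                            slice_index = s@sliceIndex, file = fname,
                            rbc_percent = unname(truthOf[s@thrombusId]))
  }
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifestPath, row.names = FALSE)
  if (is(cohort@config, "GeneratorConfig"))
    yaml::write_yaml(configToList(cohort@config),
                     file.path(dir, "generator.yaml"))
  invisible(manifestPath)
}

#' Read a cohort from a manifest
#'
#' Inverse of [writeCohort]: reads the manifest CSV and the per-slice
#' 4-volume NIfTI files. The latent oxygenation diagnostic is not part of
#' the on-disk format and is restored as `NA`.
#'
#' @param manifestPath path to `manifest.csv`.
#' @return A [ThrombusCohort-class] (config slot `NULL`).
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop("readCohort: no such manifest: ", manifestPath)
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("thrombus_id", "slice_index", "file", "rbc_percent")
  if (!all(need %in% names(man)))
    stop("readCohort: manifest must have columns ",
         paste(need, collapse = ", "))
  dir <- dirname(manifestPath)
  sliceList <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    vol <- as.array(RNifti::readNifti(file.path(dir, man$file[i])))
    channels <- array(vol[, , 1:3], dim = c(dim(vol)[1:2], 3L),
                      dimnames = list(NULL, NULL, c("r2star", "qsm", "gre")))
    sliceList[[i]] <- new("SliceImage", thrombusId = man$thrombus_id[i],
                          sliceIndex = as.integer(man$slice_index[i]),
                          channels = channels,
                          mask = (vol[, , 4L] >= 0.5) * 1)
  }
  agg <- unique(man[, c("thrombus_id", "rbc_percent")])
  thrombi <- data.frame(thrombusId = agg$thrombus_id,
                        rbcPercent = agg$rbc_percent,
                        oxygenation = NA_real_,
                        nSlices = as.integer(
                          table(man$thrombus_id)[agg$thrombus_id]),
                        stringsAsFactors = FALSE)
  new("ThrombusCohort", thrombi = thrombi, slices = sliceList,
      config = NULL, metadata = list(manifest = manifestPath))
}

## ---- report I/O ------------------------------------------------------

reportToList <- function(report) {
  stripTables <- function(m) {
    if (is.null(m)) return(NULL)
    m$confusion <- NULL; m$trueLabel <- NULL; m$predictedLabel <- NULL
    m
  }
  list(metrics = lapply(report@metrics, stripTables),
       provenance = report@provenance[
         setdiff(names(report@provenance), character())],
       nThrombi = nrow(report@predictions),
       folds = lapply(report@folds$assignment, as.character))
}

#' Write an evaluation report to disk
#'
#' Emits `<label>_report.json` (pooled metrics + provenance),
#' `<label>_predictions.csv` (one row per thrombus: id, truth, prediction,
#' fold, labels) and `<label>_roc.csv`.
#'
#' @param report an [EvaluationReport-class].
#' @param dir output directory.
#' @param label file name prefix.
#' @return invisibly, the JSON path.
#' @export
writeReport <- function(report, dir, label = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(dir, paste0(label, "_report.json"))
  jsonlite::write_json(reportToList(report), jsonPath, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  write.csv(report@predictions,
            file.path(dir, paste0(label, "_predictions.csv")),
            row.names = FALSE)
  write.csv(report@roc, file.path(dir, paste0(label, "_roc.csv")),
            row.names = FALSE)
  invisible(jsonPath)
}

## ---- end-to-end driver -----------------------------------------------

#' Run the full pipeline from a configuration
#'
#' Generates (or loads) the cohort, then cross-validates the requested
#' pipelines (`"original"`: no augmentation; `"augmented"`: the
#' three-component scheme) and, when `outDir` is set, writes reports,
#' prediction and ROC CSVs, the cohort manifest and a run log with every
#' seed. Rerunning the same configuration reproduces the reports exactly.
#'
#' @param config a [RunConfig-class] (module seeds derived from the global
#'   seed).
#' @param cohort optional pre-built [ThrombusCohort-class]; when supplied
#'   the generator stage is skipped.
#' @param verbose print stage progress.
#' @return named list of [EvaluationReport-class] (one per pipeline), with
#'   the cohort in attribute `"cohort"`.
#' @export
runPipeline <- function(config, cohort = NULL, verbose = FALSE) {
  validObject(config)
  config <- deriveModuleSeeds(config)
  if (is.null(cohort)) cohort <- generateCohort(config@generator)
  reports <- list()
  for (p in config@pipelines) {
    aug <- if (p == "augmented") config@augment
    reports[[p]] <- runCrossValidation(cohort, arch = config@arch,
                                       hp = config@hyper, augConfig = aug,
                                       evalConfig = config@eval,
                                       verbose = verbose)
    if (verbose)
      message(sprintf("pipeline '%s': thrombus MAE %.2f", p,
                      reports[[p]]@metrics$thrombusRegression$mae))
  }
  if (nzchar(config@outDir)) {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    saveConfig(config, file.path(config@outDir, "config.yaml"))
    writeCohort(cohort, file.path(config@outDir, "cohort"))
    for (p in names(reports))
      writeReport(reports[[p]], config@outDir,
                  label = paste0(config@label, "_", p))
    log <- list(globalSeed = config@seed,
                moduleSeeds = list(generator = config@generator@seed,
                                   augment = config@augment@seed,
                                   hyper = config@hyper@seed,
                                   eval = config@eval@seed),
                configHash = configHash(config),
                folds = lapply(reports[[1L]]@folds$assignment, as.character),
                nTrainPerFold = lapply(reports, function(r)
                  vapply(r@folds$details, function(d) d$nTrain, 0L)))
    jsonlite::write_json(log, file.path(config@outDir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  attr(reports, "cohort") <- cohort
  reports
}
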