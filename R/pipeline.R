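#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: either a phantom
#' configuration (simulated input) or paths to real NIfTI inputs, the
#' offset schedule, the filter window, fit subsets and solver settings,
#' and the output directory. Stage functions read and write files under
#' `outDir`, so stages can be run separately or via [runPipeline()].
#'
#' @param outDir output directory (created if needed).
#' @param phantom a [PhantomConfig-class], or `NULL` when real inputs are
#'   given.
#' @param condition phantom condition label; default `"1.5uT"`.
#' @param inputs optional named list of NIfTI paths (`series`, `s0`,
#'   `mask`, `tumor`, `nawm`, `nagm`) for real data.
#' @param schedule an [OffsetSchedule-class]; default
#'   [buildDefaultSchedule()].
#' @param windowSize adaptive filter window; default 3.
#' @param subsets a [FitSubsets-class]; default [defaultFitSubsets()].
#' @param fitCfg a [fitConfig()] list.
#' @param exportFineGrid write the (large) fine-grid corrected 4-D
#'   volumes; default `FALSE`.
#' @param seed integer seed forwarded to the phantom; default 1.
#' @return a list with class `"cestPipelineConfig"`.
#' @export
pipelineConfig <- function(outDir,
                           phantom = phantomConfig(),
                           condition = "1.5uT",
                           inputs = NULL,
                           schedule = buildDefaultSchedule(),
                           windowSize = 3L,
                           subsets = defaultFitSubsets(),
                           fitCfg = fitConfig(),
                           exportFineGrid = FALSE,
                           seed = 1L) {
  if (!is.null(phantom)) {
    phantom@seed <- as.integer(seed)
    validObject(phantom)
  }
  structure(list(outDir = outDir, phantom = phantom, condition = condition,
                 inputs = inputs, schedule = schedule,
                 windowSize = as.integer(windowSize), subsets = subsets,
                 fitCfg = fitCfg, exportFineGrid = isTRUE(exportFineGrid),
                 seed = as.integer(seed)),
            class = "cestPipelineConfig")
}

.outPath <- function(config, ...) file.path(config$outDir, ...)

.writeVol <- function(x, path) {
  storage <- x
  storage[is.na(storage)] <- NaN
  RNifti::writeNifti(RNifti::asNifti(storage), path)
  path
}

.readVol <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  a[is.nan(a)] <- NA_real_
  a
}

.readMask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim(img))
}

.stageLog <- function(config, stage, t0, extra = list()) {
  entry <- c(list(stage = stage,
                  elapsed_s = round(as.numeric(Sys.time()) - t0, 3)), extra)
  logPath <- .outPath(config, "pipeline_log.json")
  log <- if (file.exists(logPath))
    jsonlite::read_json(logPath, simplifyVector = FALSE) else list()
  log[[length(log) + 1L]] <- entry
  jsonlite::write_json(log, logPath, auto_unbox = TRUE, digits = NA)
  invisible(entry)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from, and writes its outputs under, the
#' configuration's `outDir`, so a one-shot [runPipeline()] and separately
#' invoked stages produce identical files.
#'
#' \describe{
#'   \item{`stageSimulate`}{generate the phantom: raw 4-D series, S0,
#'     analysis mask, ROI masks, schedule sidecar and ground-truth maps.}
#'   \item{`stageNormalize`}{normalize to Z-spectra and apply the 2-D
#'     adaptive noise filter; writes `zvol.nii`.}
#'   \item{`stageFit`}{voxel-wise two-pool background fit; writes one
#'     NIfTI per parameter plus residual/convergence maps and a fit
#'     configuration sidecar.}
#'   \item{`stageB0Correct`}{B0 shift map plus window-averaged corrected
#'     Z/LD volumes at the APT and NOE offsets; optionally the full
#'     fine-grid corrected spectra.}
#'   \item{`stageMaps`}{the five metric maps (LD/MTR_REX x APT/NOE and
#'     MT amplitude).}
#'   \item{`stageRoiStats`}{the per-metric ROI report CSV/JSON.}
#' }
#'
#' @param config a [pipelineConfig()] object.
#' @return invisibly, a character vector of files written.
#' @name pipelineStages
NULL

#' @rdname pipelineStages
#' @export
stageSimulate <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  ph <- generatePhantom(config$phantom, config$schedule, config$condition)
  files <- c(
    .writeVol(ph$raw@volumes, .outPath(config, "raw4d.nii")),
    .writeVol(ph$raw@s0Volume, .outPath(config, "s0.nii")),
    .writeVol(ph$mask + 0, .outPath(config, "mask.nii")),
    .writeVol(ph$rois@tumor + 0, .outPath(config, "roi_tumor.nii")),
    .writeVol(ph$rois@nawm + 0, .outPath(config, "roi_nawm.nii")),
    .writeVol(ph$rois@nagm + 0, .outPath(config, "roi_nagm.nii")),
    writeSchedule(config$schedule, .outPath(config, "schedule.json")))
  truthDir <- .outPath(config, "truth")
  dir.create(truthDir, showWarnings = FALSE)
  for (p in names(ph$truth@poolAmplitudes))
    files <- c(files, .writeVol(ph$truth@poolAmplitudes[[p]],
                                file.path(truthDir, paste0("amp_", p, ".nii"))))
  files <- c(files,
    .writeVol(ph$truth@b0ShiftMap, file.path(truthDir, "b0.nii")),
    .writeVol(ph$truth@labelMap + 0, file.path(truthDir, "labels.nii")))
  .stageLog(config, "simulate", t0,
            list(n_mask_voxels = sum(ph$mask),
                 n_tumor_voxels = sum(ph$rois@tumor)))
  invisible(files)
}

#' @rdname pipelineStages
#' @export
stageNormalize <- function(config) {
  t0 <- as.numeric(Sys.time())
  inp <- config$inputs
  seriesPath <- if (!is.null(inp)) inp$series else .outPath(config, "raw4d.nii")
  s0Path <- if (!is.null(inp)) inp$s0 else .outPath(config, "s0.nii")
  maskPath <- if (!is.null(inp)) inp$mask else .outPath(config, "mask.nii")
  raw <- RawCestSeries(.readVol(seriesPath), config$schedule,
                       .readVol(s0Path))
  mask <- .readMask(maskPath)
  zvol <- filterSeries(normalizeZSpectra(raw, mask), config$windowSize)
  files <- c(.writeVol(zvol@z, .outPath(config, "zvol.nii")),
             .writeVol(mask + 0, .outPath(config, "mask.nii")),
             writeSchedule(config$schedule, .outPath(config, "schedule.json")))
  .stageLog(config, "normalize", t0, list(n_mask_voxels = sum(mask)))
  invisible(files)
}

.loadZvol <- function(config) {
  sched <- readSchedule(.outPath(config, "schedule.json"))
  new("ZSpectrumVolume", z = .readVol(.outPath(config, "zvol.nii")),
      schedule = sched, mask = .readMask(.outPath(config, "mask.nii")))
}

.loadFitField <- function(config) {
  fitDir <- .outPath(config, "fit")
  params <- lapply(.PARAM_NAMES, function(p)
    .readVol(file.path(fitDir, paste0(p, ".nii"))))
  d3 <- dim(params[[1]])
  arr <- array(NA_real_, c(d3, 7L))
  for (i in 1:7) arr[, , , i] <- params[[i]]
  new("TwoPoolFitField", params = arr,
      residualRms = .readVol(file.path(fitDir, "residual_rms.nii")),
      converged = .readMask(file.path(fitDir, "converged.nii")),
      mask = .readMask(.outPath(config, "mask.nii")),
      nOffsetsUsed = length(config$subsets@dsOffsets) +
        length(config$subsets@mtOffsets))
}

#' @rdname pipelineStages
#' @export
stageFit <- function(config) {
  t0 <- as.numeric(Sys.time())
  zvol <- .loadZvol(config)
  field <- fitVolume(zvol, config$subsets, config$fitCfg)
  fitDir <- .outPath(config, "fit")
  dir.create(fitDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (i in seq_along(.PARAM_NAMES))
    files <- c(files, .writeVol(array(field@params[, , , i], dim(field@mask)),
                                file.path(fitDir, paste0(.PARAM_NAMES[i], ".nii"))))
  files <- c(files,
    .writeVol(field@residualRms, file.path(fitDir, "residual_rms.nii")),
    .writeVol(field@converged + 0, file.path(fitDir, "converged.nii")))
  cfgPath <- file.path(fitDir, "fit_config.json")
  jsonlite::write_json(
    list(init = as.list(config$fitCfg$init),
         lower = config$fitCfg$lower, upper = config$fitCfg$upper,
         ftol = config$fitCfg$ftol, max_iter = config$fitCfg$maxIter,
         ds_offsets = config$subsets@dsOffsets,
         mt_offsets = config$subsets@mtOffsets),
    cfgPath, auto_unbox = TRUE, digits = NA)
  files <- c(files, cfgPath)
  .stageLog(config, "fit", t0,
            list(n_converged = sum(field@converged),
                 n_fitted = sum(field@mask)))
  invisible(files)
}

#' @rdname pipelineStages
#' @export
stageB0Correct <- function(config) {
  t0 <- as.numeric(Sys.time())
  zvol <- .loadZvol(config)
  field <- .loadFitField(config)
  corrected <- correctB0(zvol, field)
  w <- .windowedMetrics(corrected, 3.5, -3.5, 0.2)
  d3 <- corrected@spatialDim
  put <- function(v) {
    a <- array(NA_real_, d3)
    a[corrected@voxelIndex] <- v
    a
  }
  files <- c(
    .writeVol(corrected@b0ShiftMap, .outPath(config, "b0_shift.nii")),
    .writeVol(put(w$zApt), .outPath(config, "zw_apt.nii")),
    .writeVol(put(w$zNoe), .outPath(config, "zw_noe.nii")),
    .writeVol(put(w$ldApt), .outPath(config, "ldw_apt.nii")),
    .writeVol(put(w$ldNoe), .outPath(config, "ldw_noe.nii")))
  if (config$exportFineGrid) {
    fine <- array(NA_real_, c(d3, length(corrected@grid)))
    nvox <- prod(d3)
    for (j in seq_along(corrected@grid))
      fine[corrected@voxelIndex + (j - 1L) * nvox] <- corrected@zCorrected[, j]
    files <- c(files, .writeVol(fine, .outPath(config, "z_finegrid.nii")))
  }
  .stageLog(config, "b0correct", t0,
            list(n_corrected = length(corrected@voxelIndex)))
  invisible(files)
}

#' @rdname pipelineStages
#' @export
stageMaps <- function(config) {
  t0 <- as.numeric(Sys.time())
  zApt <- .readVol(.outPath(config, "zw_apt.nii"))
  zNoe <- .readVol(.outPath(config, "zw_noe.nii"))
  ldApt <- .readVol(.outPath(config, "ldw_apt.nii"))
  ldNoe <- .readVol(.outPath(config, "ldw_noe.nii"))
  aMt <- .readVol(.outPath(config, "fit", "aMt.nii"))
  maps <- list(
    LD_APT = ldApt,
    LD_NOE = ldNoe,
    MTRREX_APT = computeMtrRex(zApt + ldApt, zApt),
    MTRREX_NOE = computeMtrRex(zNoe + ldNoe, zNoe),
    MT_AMPLITUDE = aMt)
  mapsDir <- .outPath(config, "maps")
  dir.create(mapsDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(maps)) {
    base <- sprintf("%s_%s", tolower(nm), config$condition)
    files <- c(files,
               .writeVol(maps[[nm]], file.path(mapsDir, paste0(base, ".nii"))))
    sidecar <- file.path(mapsDir, paste0(base, ".json"))
    jsonlite::write_json(
      list(metric_name = nm,
           offset_ppm = switch(nm, LD_APT = , MTRREX_APT = 3.5,
                               LD_NOE = , MTRREX_NOE = -3.5, NULL),
           b1_label = config$condition),
      sidecar, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, sidecar)
  }
  .stageLog(config, "maps", t0, list(metrics = names(maps)))
  invisible(files)
}

#' @rdname pipelineStages
#' @export
stageRoiStats <- function(config) {
  t0 <- as.numeric(Sys.time())
  inp <- config$inputs
  tumorPath <- if (!is.null(inp)) inp$tumor else .outPath(config, "roi_tumor.nii")
  nawmPath <- if (!is.null(inp)) inp$nawm else .outPath(config, "roi_nawm.nii")
  nagmPath <- if (!is.null(inp)) inp$nagm else .outPath(config, "roi_nagm.nii")
  readRoi <- function(p, like) {
    if (is.null(p) || !file.exists(p)) array(FALSE, dim(like)) else .readMask(p)
  }
  mapsDir <- .outPath(config, "maps")
  maps <- list()
  for (nm in .METRIC_NAMES) {
    base <- sprintf("%s_%s", tolower(nm), config$condition)
    vals <- .readVol(file.path(mapsDir, paste0(base, ".nii")))
    maps[[nm]] <- new("MetricMap", values = vals, metricName = nm,
                      offset = switch(nm, LD_APT = , MTRREX_APT = 3.5,
                                      LD_NOE = , MTRREX_NOE = -3.5,
                                      NA_real_),
                      b1Label = config$condition)
  }
  tumor <- readRoi(tumorPath, maps[[1]]@values)
  rois <- RoiSet(tumor,
                 readRoi(nawmPath, maps[[1]]@values),
                 readRoi(nagmPath, maps[[1]]@values))
  report <- buildRoiReport(maps, rois)
  csvPath <- .outPath(config, "roi_report.csv")
  utils::write.csv(report, csvPath, row.names = FALSE)
  jsonPath <- .outPath(config, "roi_report.json")
  jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  .stageLog(config, "roistats", t0, list(n_rows = nrow(report)))
  invisible(c(csvPath, jsonPath))
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (when a phantom is configured),
#' normalize + filter, two-pool fit, B0 correction, metric maps, ROI
#' report — and writes `manifest.json` listing every output file with its
#' MD5 checksum plus the effective configuration. Stage validation errors
#' abort with a stage-named diagnostic; per-voxel sentinel flags never
#' abort.
#'
#' @param config a [pipelineConfig()] object.
#' @return invisibly, the manifest as a list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "cestPipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- .outPath(config, "pipeline_log.json")
  if (file.exists(logPath)) unlink(logPath)
  files <- character()
  runStage <- function(name, fun) {
    out <- tryCatch(fun(config), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    files <<- c(files, out)
  }
  if (!is.null(config$phantom)) runStage("simulate", stageSimulate)
  runStage("normalize", stageNormalize)
  runStage("fit", stageFit)
  runStage("b0correct", stageB0Correct)
  runStage("maps", stageMaps)
  runStage("roistats", stageRoiStats)
  prefix <- paste0(config$outDir, .Platform$file.sep)
  rel <- ifelse(startsWith(files, prefix),
                substring(files, nchar(prefix) + 1L), files)
  manifest <- list(
    files = lapply(seq_along(files), function(i)
      list(path = rel[i],
           md5 = unname(tools::md5sum(files[i])))),
    config = list(condition = config$condition,
                  window_size = config$windowSize,
                  seed = config$seed,
                  n_offsets = length(config$schedule@offsets),
                  ds_offsets = config$subsets@dsOffsets,
                  mt_offsets = config$subsets@mtOffsets))
  jsonlite::write_json(manifest, .outPath(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
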