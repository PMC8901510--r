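#' Construct an offset schedule
#'
#' @param offsets numeric vector of saturation offsets, ppm.
#' @param normalizationOffset far off-resonance normalization offset, ppm
#'   (magnitude >= 100); default -300.
#' @param nDiscardLeading leading normalization-offset images discarded
#'   before the retained S0; default 1.
#' @return an [OffsetSchedule-class].
#' @examples
#' sched <- OffsetSchedule(c(-3.5, 0, 3.5))
#' offsets(sched)
#' @export
OffsetSchedule <- function(offsets, normalizationOffset = -300,
                           nDiscardLeading = 1L) {
  new("OffsetSchedule", offsets = as.numeric(offsets),
      normalizationOffset = as.numeric(normalizationOffset),
      nDiscardLeading = as.integer(nDiscardLeading))
}

#' Construct a saturation train
#'
#' @param nPulses number of RF pulses.
#' @param pulseDuration single pulse duration, ms.
#' @param interpulseDelay delay between pulses, ms.
#' @param rmsB1 RMS B1 over the train, microtesla (metadata only).
#' @return a [SaturationTrain-class].
#' @examples
#' tr <- SaturationTrain(80, 20, 20, rmsB1 = 1.5)
#' trainTotalDuration(tr)  # 3.2 s
#' @export
SaturationTrain <- function(nPulses, pulseDuration, interpulseDelay,
                            rmsB1 = NA_real_) {
  new("SaturationTrain", nPulses = as.integer(nPulses),
      pulseDuration = as.numeric(pulseDuration),
      interpulseDelay = as.numeric(interpulseDelay),
      rmsB1 = as.numeric(rmsB1))
}

#' @rdname offsets
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' Schedule accessors
#'
#' `offsets()` returns the saturation offsets in ppm (acquisition order);
#' `normalizationOffset()` the far off-resonance normalization offset;
#' `nDiscardLeading()` how many leading normalization-offset images are
#' discarded; `sortedOrder()` the permutation taking acquisition order to
#' ascending ppm order.
#'
#' @param x an [OffsetSchedule-class] (or an object carrying one).
#' @return numeric vector / scalar / integer permutation as appropriate.
#' @export
setMethod("offsets", "OffsetSchedule", function(x) x@offsets)

#' @rdname offsets
#' @export
setMethod("offsets", "ZSpectrumVolume", function(x) x@schedule@offsets)

#' @rdname offsets
#' @export
setMethod("offsets", "RawCestSeries", function(x) x@schedule@offsets)

#' @rdname offsets
#' @export
normalizationOffset <- function(x) x@normalizationOffset

#' @rdname offsets
#' @export
nDiscardLeading <- function(x) x@nDiscardLeading

#' @rdname offsets
#' @export
sortedOrder <- function(x) order(x@offsets)

#' Default saturation offset schedule
#'
#' The dense symmetric Z-spectrum sampling used throughout the package:
#' +/-100 ppm; +/-50 to +/-20 ppm in 10 ppm steps; +/-10 to +/-5 ppm in
#' 0.5 ppm steps (so the MT background subset +/-9.5 and +/-8.5 ppm
#' exists); +/-4 to +/-1 ppm in 0.5 ppm steps; +/-0.5 to 0 ppm in 0.25 ppm
#' steps — 51 offsets in all, stored descending from +100 to -100 —
#' together with the -300 ppm normalization convention (two images
#' acquired there, the first discarded, the second used as S0).
#'
#' @return an [OffsetSchedule-class] with 51 offsets.
#' @examples
#' sched <- buildDefaultSchedule()
#' length(offsets(sched))
#' @export
buildDefaultSchedule <- function() {
  pos <- c(100, seq(50, 20, by = -10), seq(10, 5, by = -0.5),
           seq(4, 1, by = -0.5), 0.5, 0.25)
  OffsetSchedule(c(pos, 0, -rev(pos)),
                 normalizationOffset = -300, nDiscardLeading = 1L)
}

#' Saturation-train timing
#'
#' `trainTotalDuration()` is the total saturation time in seconds,
#' `nPulses * (pulseDuration + interpulseDelay)` converted from ms;
#' `trainDutyCycle()` is the dimensionless duty fraction
#' `pulseDuration / (pulseDuration + interpulseDelay)`.
#'
#' @param train a [SaturationTrain-class].
#' @return a single number (seconds, or a fraction in (0, 1]).
#' @examples
#' trainTotalDuration(SaturationTrain(80, 20, 20))  # 3.2
#' trainDutyCycle(SaturationTrain(80, 20, 20))      # 0.5
#' @export
trainTotalDuration <- function(train) {
  stopifnot(is(train, "SaturationTrain"))
  validObject(train)
  train@nPulses * (train@pulseDuration + train@interpulseDelay) / 1000
}

#' @rdname trainTotalDuration
#' @export
trainDutyCycle <- function(train) {
  stopifnot(is(train, "SaturationTrain"))
  validObject(train)
  train@pulseDuration / (train@pulseDuration + train@interpulseDelay)
}

#' Slice thickness from slab field of view
#'
#' Trivial acquisition-geometry arithmetic: slab extent divided by the
#' number of slices.
#'
#' @param fovMm slab field of view along the slice direction, mm.
#' @param nSlices number of slices.
#' @return slice thickness in mm.
#' @examples
#' sliceThickness(42, 14)  # 3
#' @export
sliceThickness <- function(fovMm, nSlices) {
  stopifnot(fovMm > 0, nSlices >= 1)
  fovMm / nSlices
}

#' Read / write a schedule sidecar
#'
#' Schedules are serialized as plain JSON: the ppm offsets in acquisition
#' order plus the normalization-offset metadata.
#'
#' @param schedule an [OffsetSchedule-class].
#' @param path file path of the JSON sidecar.
#' @return `writeSchedule()` returns `path` invisibly; `readSchedule()`
#'   returns the reconstructed [OffsetSchedule-class].
#' @export
writeSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "OffsetSchedule"))
  jsonlite::write_json(
    list(offsets_ppm = schedule@offsets,
         normalization_offset_ppm = schedule@normalizationOffset,
         n_discard_leading = schedule@nDiscardLeading),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  OffsetSchedule(x$offsets_ppm, x$normalization_offset_ppm,
                 x$n_discard_leading)
}
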