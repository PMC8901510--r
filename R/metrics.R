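#' Lorentzian-difference metric
#'
#' \eqn{LD = Z_{ref} - Z}: the fitted background minus the measured
#' Z-value. Positive where a saturation-transfer effect depresses Z below
#' the background; negative values are permitted.
#'
#' @param zref background (reference) Z value(s).
#' @param z measured Z value(s).
#' @return `zref - z`, vectorized.
#' @examples
#' computeLd(0.8, 0.75)  # 0.05
#' @export
computeLd <- function(zref, z) {
  zref - z
}

#' Inverse magnetization transfer ratio
#'
#' \eqn{MTR_{REX} = 1/Z - 1/Z_{ref}}: the spillover-compensated inverse
#' difference metric. Values where either argument is at or below `eps`
#' (near full saturation) are flagged missing (`NA`) rather than clipped,
#' so downstream statistics are not biased by fabricated values.
#'
#' @param zref background (reference) Z value(s).
#' @param z measured Z value(s).
#' @param eps reciprocal guard; default 1e-3.
#' @return `1/z - 1/zref`, vectorized, `NA` where guarded.
#' @examples
#' computeMtrRex(0.8, 0.5)  # 0.75
#' @export
computeMtrRex <- function(zref, z, eps = 1e-3) {
  out <- 1 / z - 1 / zref
  out[!is.na(z) & !is.na(zref) & (z <= eps | zref <= eps)] <- NA_real_
  out
}

#' Extract APT/NOE metric maps from corrected spectra
#'
#' Evaluates, per corrected voxel, the window-averaged corrected Z and LD
#' at +3.5 ppm (APT) and -3.5 ppm (NOE) (closed +/-0.2 ppm window, 5 grid
#' points), forms `Zref = Z + LD`, and computes the LD and MTR_REX maps
#' from the window-averaged quantities. The MT amplitude map is taken
#' directly from the fitted `aMt` parameter. Voxels hitting the MTR_REX
#' reciprocal guard are flagged `NA` and their count reported.
#'
#' @param corrected a [CorrectedSpectra-class].
#' @param fitField the matching [TwoPoolFitField-class].
#' @param b1Label annotation copied onto every map; default `""`.
#' @param aptOffset,noeOffset evaluation offsets, ppm; defaults +3.5/-3.5.
#' @param halfWidth window half width, ppm; default 0.2.
#' @param eps reciprocal guard for MTR_REX; default 1e-3.
#' @return named list of five [MetricMap-class] objects: `LD_APT`,
#'   `LD_NOE`, `MTRREX_APT`, `MTRREX_NOE`, `MT_AMPLITUDE`.
#' @export
extractMetricMaps <- function(corrected, fitField, b1Label = "",
                              aptOffset = 3.5, noeOffset = -3.5,
                              halfWidth = 0.2, eps = 1e-3) {
  stopifnot(is(corrected, "CorrectedSpectra"), is(fitField, "TwoPoolFitField"))
  d3 <- corrected@spatialDim
  if (!all(d3 == dim(fitField@mask)))
    stop("corrected spectra and fit field are on different voxel grids")
  w <- .windowedMetrics(corrected, aptOffset, noeOffset, halfWidth)
  maps <- .mapsFromWindowed(w, d3, corrected@voxelIndex, eps, b1Label,
                            aptOffset, noeOffset)
  amt <- fitParam(fitField, "aMt")
  maps$MT_AMPLITUDE <- new("MetricMap", values = amt,
                           metricName = "MT_AMPLITUDE", offset = NA_real_,
                           b1Label = b1Label)
  maps[c("LD_APT", "LD_NOE", "MTRREX_APT", "MTRREX_NOE", "MT_AMPLITUDE")]
}

# window-averaged corrected Z / LD at the APT and NOE offsets, per voxel row
.windowedMetrics <- function(corrected, aptOffset, noeOffset, halfWidth) {
  g <- corrected@grid
  ia <- .windowIdx(g, aptOffset, halfWidth)
  io <- .windowIdx(g, noeOffset, halfWidth)
  list(
    zApt = rowMeans(corrected@zCorrected[, ia, drop = FALSE]),
    zNoe = rowMeans(corrected@zCorrected[, io, drop = FALSE]),
    ldApt = rowMeans(corrected@ldCorrected[, ia, drop = FALSE]),
    ldNoe = rowMeans(corrected@ldCorrected[, io, drop = FALSE]))
}

# assemble the four LD/MTR_REX MetricMaps from windowed vectors
.mapsFromWindowed <- function(w, d3, voxelIndex, eps, b1Label,
                              aptOffset, noeOffset) {
  zrefApt <- w$zApt + w$ldApt
  zrefNoe <- w$zNoe + w$ldNoe
  mrApt <- computeMtrRex(zrefApt, w$zApt, eps)
  mrNoe <- computeMtrRex(zrefNoe, w$zNoe, eps)
  nFlag <- sum(is.na(mrApt)) + sum(is.na(mrNoe))
  if (nFlag > 0)
    message(sprintf(
      "extractMetricMaps: %d voxel value(s) flagged missing by the %s",
      nFlag, "MTR_REX reciprocal guard"))
  toMap <- function(v, name, off) {
    a <- array(NA_real_, d3)
    a[voxelIndex] <- v
    new("MetricMap", values = a, metricName = name, offset = off,
        b1Label = b1Label)
  }
  list(LD_APT = toMap(w$ldApt, "LD_APT", aptOffset),
       LD_NOE = toMap(w$ldNoe, "LD_NOE", noeOffset),
       MTRREX_APT = toMap(mrApt, "MTRREX_APT", aptOffset),
       MTRREX_NOE = toMap(mrNoe, "MTRREX_NOE", noeOffset))
}

#' @rdname metricValues
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' Metric map accessors
#'
#' @param x a [MetricMap-class].
#' @return `metricValues()` the 3-D value array; `metricName()` the metric
#'   label; `b1Label()` the saturation-power annotation.
#' @export
setMethod("metricValues", "MetricMap", function(x) x@values)

#' @rdname metricValues
#' @export
metricName <- function(x) x@metricName

#' @rdname metricValues
#' @export
b1Label <- function(x) x@b1Label
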