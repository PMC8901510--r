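#' @import methods
NULL

# ---------------------------------------------------------------------------
# OffsetSchedule
# ---------------------------------------------------------------------------

#' Saturation frequency offset schedule
#'
#' Ordered saturation frequency offsets (ppm relative to water, positive =
#' downfield) together with the far off-resonance normalization convention:
#' the offset at which the unsaturated reference image \eqn{S_0} is acquired
#' and how many leading images at that offset are discarded before the
#' retained \eqn{S_0}.
#'
#' @slot offsets numeric vector of saturation offsets in ppm, acquisition
#'   order. Unique after rounding to 0.01 ppm.
#' @slot normalizationOffset single ppm value, magnitude >= 100 ppm so that
#'   saturation effects are negligible by construction.
#' @slot nDiscardLeading number of leading normalization-offset images
#'   discarded before the retained \eqn{S_0} (the first has not reached
#'   steady state).
#'
#' @seealso [buildDefaultSchedule()]
#' @export
setClass("OffsetSchedule",
  representation(
    offsets = "numeric",
    normalizationOffset = "numeric",
    nDiscardLeading = "integer"
  ),
  prototype(normalizationOffset = -300, nDiscardLeading = 1L)
)

setValidity("OffsetSchedule", function(object) {
  o <- object@offsets
  msg <- character()
  if (length(o) < 1L || !all(is.finite(o)))
    msg <- c(msg, "offsets must be a non-empty finite numeric vector")
  if (anyDuplicated(round(o, 2)))
    msg <- c(msg, "offsets must be unique after rounding to 0.01 ppm")
  if (length(object@normalizationOffset) != 1L ||
      !is.finite(object@normalizationOffset) ||
      abs(object@normalizationOffset) < 100)
    msg <- c(msg, "normalizationOffset must have magnitude >= 100 ppm")
  if (length(object@nDiscardLeading) != 1L || object@nDiscardLeading < 0L)
    msg <- c(msg, "nDiscardLeading must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SaturationTrain
# ---------------------------------------------------------------------------

#' Pulsed saturation train timing
#'
#' Timing bookkeeping for a pulsed RF presaturation module: a train of
#' identical pulses separated by fixed interpulse delays. Only the timing
#' arithmetic is modelled; pulse shapes are out of scope. The RMS B1 over
#' the train is carried as metadata.
#'
#' @slot nPulses number of RF pulses (>= 1).
#' @slot pulseDuration single pulse duration, ms.
#' @slot interpulseDelay delay between consecutive pulses, ms.
#' @slot rmsB1 root-mean-square B1 over the train, microtesla (metadata only).
#'
#' @seealso [trainTotalDuration()], [trainDutyCycle()]
#' @export
setClass("SaturationTrain",
  representation(
    nPulses = "integer",
    pulseDuration = "numeric",
    interpulseDelay = "numeric",
    rmsB1 = "numeric"
  ),
  prototype(rmsB1 = NA_real_)
)

setValidity("SaturationTrain", function(object) {
  msg <- character()
  if (length(object@nPulses) != 1L || is.na(object@nPulses) ||
      object@nPulses < 1L)
    msg <- c(msg, "nPulses must be a single integer >= 1")
  if (length(object@pulseDuration) != 1L || !is.finite(object@pulseDuration) ||
      object@pulseDuration <= 0)
    msg <- c(msg, "pulseDuration must be a single positive value (ms)")
  if (length(object@interpulseDelay) != 1L ||
      !is.finite(object@interpulseDelay) || object@interpulseDelay < 0)
    msg <- c(msg, "interpulseDelay must be a single non-negative value (ms)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Raw series and Z-spectrum volume
# ---------------------------------------------------------------------------

#' Raw saturated CEST image series
#'
#' A 4-D stack of saturated volumes (x, y, z, acquisition index) in arbitrary
#' scanner units, plus the retained normalization volume \eqn{S_0} and the
#' offset schedule describing the acquisition axis. The leading dummy
#' image(s) at the normalization offset are assumed already discarded, so
#' the fourth dimension equals the schedule length.
#'
#' @slot volumes 4-D numeric array, last axis matching `offsets(schedule)`.
#' @slot schedule an [OffsetSchedule-class].
#' @slot s0Volume 3-D numeric array, the retained \eqn{S_0} image.
#' @export
setClass("RawCestSeries",
  representation(
    volumes = "array",
    schedule = "OffsetSchedule",
    s0Volume = "array"
  )
)

setValidity("RawCestSeries", function(object) {
  msg <- character()
  dv <- dim(object@volumes)
  ds <- dim(object@s0Volume)
  if (length(dv) != 4L)
    msg <- c(msg, "volumes must be a 4-D array (x, y, z, offset)")
  if (length(ds) != 3L)
    msg <- c(msg, "s0Volume must be a 3-D array")
  if (length(dv) == 4L && length(ds) == 3L && !all(dv[1:3] == ds))
    msg <- c(msg, "spatial dimensions of volumes and s0Volume differ")
  if (length(dv) == 4L && dv[4L] != length(object@schedule@offsets))
    msg <- c(msg, sprintf(
      "acquisition axis length (%d) does not match schedule length (%d)",
      dv[4L], length(object@schedule@offsets)))
  if (length(msg)) msg else TRUE
})

#' Normalized Z-spectrum volume
#'
#' Dimensionless Z-spectra \eqn{Z(\Delta\omega) = S_{sat}(\Delta\omega)/S_0}
#' on a voxel grid, with the offset axis ordered as in the schedule and a
#' boolean analysis mask. Voxels outside the mask carry `NA`.
#'
#' @slot z 4-D numeric array (x, y, z, offset index), dimensionless.
#' @slot schedule an [OffsetSchedule-class].
#' @slot mask 3-D logical array; `TRUE` marks analysis voxels.
#' @export
setClass("ZSpectrumVolume",
  representation(
    z = "array",
    schedule = "OffsetSchedule",
    mask = "array"
  )
)

setValidity("ZSpectrumVolume", function(object) {
  msg <- character()
  dz <- dim(object@z)
  dm <- dim(object@mask)
  if (length(dz) != 4L)
    msg <- c(msg, "z must be a 4-D array (x, y, z, offset)")
  if (!is.logical(object@mask) || length(dm) != 3L)
    msg <- c(msg, "mask must be a 3-D logical array")
  if (length(dz) == 4L && length(dm) == 3L && !all(dz[1:3] == dm))
    msg <- c(msg, "spatial dimensions of z and mask differ")
  if (length(dz) == 4L && dz[4L] != length(object@schedule@offsets))
    msg <- c(msg, "offset axis length does not match schedule length")
  if (length(dz) == 4L && length(dm) == 3L && all(dz[1:3] == dm) &&
      any(object@mask)) {
    zin <- object@z[.maskIdx4(object@mask, dz[4L])]
    if (anyNA(zin) || any(!is.finite(zin)))
      msg <- c(msg, "z must be finite inside the mask")
    else if (any(zin < 0))
      msg <- c(msg, "z must be non-negative inside the mask")
  }
  if (length(msg)) msg else TRUE
})

# linear indices of all (voxel-in-mask, offset) entries of a 4-D array
.maskIdx4 <- function(mask, nOffsets) {
  v <- which(mask)
  nvox <- prod(dim(mask))
  as.vector(outer(v, (seq_len(nOffsets) - 1L) * nvox, `+`))
}

# ---------------------------------------------------------------------------
# Lorentzian pools and two-pool fits
# ---------------------------------------------------------------------------

#' A single Lorentzian saturation pool
#'
#' One Lorentzian line in a Z-spectrum model, parameterized by its peak
#' amplitude, full width at half maximum (FWHM) and center frequency.
#'
#' @slot amplitude peak amplitude A, dimensionless (0-1 scale), >= 0.
#' @slot width FWHM L, ppm, > 0.
#' @slot center center frequency delta, ppm relative to water.
#' @export
setClass("LorentzianPool",
  representation(amplitude = "numeric", width = "numeric", center = "numeric")
)

setValidity("LorentzianPool", function(object) {
  msg <- character()
  if (length(object@amplitude) != 1L || !is.finite(object@amplitude) ||
      object@amplitude < 0)
    msg <- c(msg, "amplitude must be a single finite value >= 0")
  if (length(object@width) != 1L || !is.finite(object@width) ||
      object@width <= 0)
    msg <- c(msg, "width (FWHM) must be a single positive value")
  if (length(object@center) != 1L || !is.finite(object@center))
    msg <- c(msg, "center must be a single finite ppm value")
  if (length(msg)) msg else TRUE
})

#' Two-pool Lorentzian background fit of one Z-spectrum
#'
#' Result of fitting the water (direct saturation) + semi-solid MT
#' background model
#' \deqn{Z_{ref}(\Delta\omega) = 1 - A_w \frac{L_w^2/4}{L_w^2/4 +
#'   (\Delta\omega-\delta_w)^2} - A_{MT} \frac{L_{MT}^2/4}{L_{MT}^2/4 +
#'   (\Delta\omega-\delta_{MT})^2} + b}
#' to one voxel's Z-spectrum, restricted to the background offset subsets.
#' A failed fit is represented by a sentinel object with `converged = FALSE`
#' and `NA` parameters; it is never an error.
#'
#' @slot water water (direct saturation) [LorentzianPool-class].
#' @slot mt semi-solid MT [LorentzianPool-class].
#' @slot baseline constant baseline shift b, dimensionless.
#' @slot residualRms root-mean-square fit residual over the points used.
#' @slot converged logical convergence flag.
#' @slot nOffsetsUsed number of offsets entering the fit.
#' @export
setClass("TwoPoolFit",
  representation(
    water = "LorentzianPool",
    mt = "LorentzianPool",
    baseline = "numeric",
    residualRms = "numeric",
    converged = "logical",
    nOffsetsUsed = "integer"
  )
)

setValidity("TwoPoolFit", function(object) {
  msg <- character()
  if (length(object@converged) != 1L || is.na(object@converged))
    msg <- c(msg, "converged must be TRUE or FALSE")
  if (isTRUE(object@converged)) {
    if (!is.finite(object@residualRms) || object@residualRms < 0)
      msg <- c(msg, "residualRms of a converged fit must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Background-fit offset subsets
#'
#' The offsets used to constrain the two-pool background fit: a narrow set
#' around water for direct saturation and a wide set for the broad MT pool.
#' The two sets are disjoint and both must exist in the schedule (matched
#' within 0.01 ppm).
#'
#' @slot dsOffsets ppm offsets constraining direct saturation.
#' @slot mtOffsets ppm offsets constraining the MT pool.
#' @seealso [defaultFitSubsets()]
#' @export
setClass("FitSubsets",
  representation(dsOffsets = "numeric", mtOffsets = "numeric")
)

setValidity("FitSubsets", function(object) {
  msg <- character()
  if (!all(is.finite(object@dsOffsets)) || !all(is.finite(object@mtOffsets)))
    msg <- c(msg, "subset offsets must be finite")
  if (length(intersect(round(object@dsOffsets, 2),
                       round(object@mtOffsets, 2))))
    msg <- c(msg, "dsOffsets and mtOffsets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Voxel field of two-pool fits
#'
#' Per-voxel parameters of the two-pool background fit stored as parameter
#' maps: a 4-D array whose last axis runs over the seven parameters
#' `aWater, lWater, dWater, aMt, lMt, dMt, b`, plus residual and
#' convergence maps. Non-fitted (unmasked or sentinel) voxels carry `NA`
#' parameters.
#'
#' @slot params 4-D numeric array (x, y, z, parameter).
#' @slot residualRms 3-D numeric array of per-voxel RMS residuals.
#' @slot converged 3-D logical array.
#' @slot mask 3-D logical analysis mask the fit was run on.
#' @slot nOffsetsUsed offsets per voxel entering each fit.
#' @export
setClass("TwoPoolFitField",
  representation(
    params = "array",
    residualRms = "array",
    converged = "array",
    mask = "array",
    nOffsetsUsed = "integer"
  )
)

.PARAM_NAMES <- c("aWater", "lWater", "dWater", "aMt", "lMt", "dMt", "b")

setValidity("TwoPoolFitField", function(object) {
  msg <- character()
  dp <- dim(object@params)
  if (length(dp) != 4L || dp[4L] != 7L)
    msg <- c(msg, "params must be a 4-D array with 7 parameter planes")
  if (length(dp) == 4L &&
      (!all(dp[1:3] == dim(object@residualRms)) ||
       !all(dp[1:3] == dim(object@converged)) ||
       !all(dp[1:3] == dim(object@mask))))
    msg <- c(msg, "params, residualRms, converged and mask dims must agree")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# B0-corrected spectra
# ---------------------------------------------------------------------------

#' B0-corrected fine-grid spectra
#'
#' Per-voxel Z and Lorentzian-difference (LD) spectra after B0 correction:
#' each voxel's sampled spectrum is translated by its fitted B0 shift and
#' linearly resampled onto a fixed fine ppm grid. Only masked voxels are
#' stored, as rows of the spectral matrices; `voxelIndex` maps rows back to
#' linear voxel indices of the 3-D grid.
#'
#' @slot grid fine ppm grid, -100 to 100 at 0.1 ppm spacing.
#' @slot zCorrected matrix (masked voxel x grid point) of corrected Z.
#' @slot ldCorrected matrix of corrected LD (= Zref - Z) on the same grid.
#' @slot b0ShiftMap 3-D ppm map of the applied per-voxel shifts.
#' @slot voxelIndex linear indices of the stored voxels.
#' @slot spatialDim the 3-D grid dimensions.
#' @export
setClass("CorrectedSpectra",
  representation(
    grid = "numeric",
    zCorrected = "matrix",
    ldCorrected = "matrix",
    b0ShiftMap = "array",
    voxelIndex = "integer",
    spatialDim = "integer"
  )
)

setValidity("CorrectedSpectra", function(object) {
  msg <- character()
  g <- object@grid
  if (length(g) < 2L || any(abs(diff(g) - 0.1) > 1e-9))
    msg <- c(msg, "grid spacing must be exactly 0.1 ppm")
  if (length(g) >= 2L && (g[1L] > -100 + 1e-9 || g[length(g)] < 100 - 1e-9))
    msg <- c(msg, "grid must cover [-100, 100] ppm")
  if (ncol(object@zCorrected) != length(g) ||
      ncol(object@ldCorrected) != length(g))
    msg <- c(msg, "spectral matrices must have one column per grid point")
  if (nrow(object@zCorrected) != length(object@voxelIndex) ||
      nrow(object@ldCorrected) != length(object@voxelIndex))
    msg <- c(msg, "spectral matrices must have one row per stored voxel")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Metric maps and ROIs
# ---------------------------------------------------------------------------

.METRIC_NAMES <- c("LD_APT", "LD_NOE", "MTRREX_APT", "MTRREX_NOE",
                   "MT_AMPLITUDE")

#' A 3-D map of one CEST metric
#'
#' One scalar metric per voxel: LD or MTR_REX evaluated at a named offset
#' (+3.5 ppm for APT, -3.5 ppm for NOE), or the fitted MT pool amplitude.
#' Voxels outside the analysis mask, or flagged during computation, carry
#' `NA`.
#'
#' @slot values 3-D numeric array, dimensionless.
#' @slot metricName one of `"LD_APT"`, `"LD_NOE"`, `"MTRREX_APT"`,
#'   `"MTRREX_NOE"`, `"MT_AMPLITUDE"`.
#' @slot offset evaluation offset in ppm (`NA` for `MT_AMPLITUDE`).
#' @slot b1Label free-text saturation-power annotation (e.g. `"1.5uT"`).
#' @export
setClass("MetricMap",
  representation(
    values = "array",
    metricName = "character",
    offset = "numeric",
    b1Label = "character"
  ),
  prototype(b1Label = "")
)

setValidity("MetricMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  if (length(object@metricName) != 1L ||
      !object@metricName %in% .METRIC_NAMES)
    msg <- c(msg, paste0("metricName must be one of: ",
                         paste(.METRIC_NAMES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Region-of-interest mask set
#'
#' The three pairwise-disjoint ROI masks of the heterogeneity analysis:
#' tumor, contralateral normal-appearing white matter (NAWM) and
#' grey matter (NAGM), all on the metric-map voxel grid. A mask may be
#' empty (all-`FALSE`), in which case statistics depending on it are
#' reported as missing.
#'
#' @slot tumor 3-D logical array.
#' @slot nawm 3-D logical array.
#' @slot nagm 3-D logical array.
#' @export
setClass("RoiSet",
  representation(tumor = "array", nawm = "array", nagm = "array")
)

setValidity("RoiSet", function(object) {
  msg <- character()
  for (nm in c("tumor", "nawm", "nagm")) {
    m <- slot(object, nm)
    if (!is.logical(m) || length(dim(m)) != 3L)
      msg <- c(msg, sprintf("%s must be a 3-D logical array", nm))
  }
  if (!length(msg)) {
    d <- dim(object@tumor)
    if (!all(d == dim(object@nawm)) || !all(d == dim(object@nagm)))
      msg <- c(msg, "ROI masks must share one voxel grid")
    else if (any(object@tumor & object@nawm) ||
             any(object@tumor & object@nagm) ||
             any(object@nawm & object@nagm))
      msg <- c(msg, "ROI masks must be pairwise disjoint")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Phantom configuration and ground truth
# ---------------------------------------------------------------------------

#' Synthetic phantom configuration
#'
#' Configuration of the multi-pool synthetic CEST phantom: voxel grid and
#' tissue geometry (white-matter background inside an ellipsoidal brain,
#' grey-matter shell, spherical tumor), a per-tissue pool table for each
#' saturation-power condition, a smooth B0 offset field, the noise level
#' and the random seed. All pool amplitudes are synthetic defaults chosen
#' for qualitative realism, not measurements.
#'
#' @slot gridShape 3-D voxel grid dimensions.
#' @slot tumorRadius tumor sphere radius in voxels.
#' @slot tumorCenter tumor sphere center, voxel coordinates.
#' @slot tissueTables named list (one per B1 condition label) of pool
#'   tables: data frames with columns `tissue`, `pool`, `A`, `L`, `delta`.
#' @slot b0Coef coefficients `(c0, cx, cy, cz)` of a linear B0 field in
#'   ppm over coordinates normalized to \eqn{[-1, 1]}.
#' @slot noiseSigma additive Gaussian noise SD on the normalized signal.
#' @slot s0Level mean intensity of the \eqn{S_0} image, scanner units.
#' @slot seed integer random seed.
#' @seealso [phantomConfig()], [defaultTissueTable()], [generatePhantom()]
#' @export
setClass("PhantomConfig",
  representation(
    gridShape = "integer",
    tumorRadius = "numeric",
    tumorCenter = "numeric",
    tissueTables = "list",
    b0Coef = "numeric",
    noiseSigma = "numeric",
    s0Level = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    msg <- c(msg, "gridShape must be three dimensions, each >= 4 voxels")
  if (length(object@b0Coef) != 4L || !all(is.finite(object@b0Coef)))
    msg <- c(msg, "b0Coef must be four finite coefficients (c0, cx, cy, cz)")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0")
  for (lbl in names(object@tissueTables)) {
    tab <- object@tissueTables[[lbl]]
    if (!all(c("tissue", "pool", "A", "L", "delta") %in% names(tab))) {
      msg <- c(msg, sprintf("tissue table '%s' lacks required columns", lbl))
      next
    }
    if (any(tab$A < 0) || any(tab$L <= 0))
      msg <- c(msg, sprintf(
        "tissue table '%s': amplitudes must be >= 0 and widths > 0", lbl))
    sums <- tapply(tab$A, tab$tissue, sum)
    if (any(sums >= 1))
      msg <- c(msg, sprintf(
        "tissue table '%s': pool amplitudes must sum to < 1 per tissue (Z stays positive); violated for %s",
        lbl, paste(names(sums)[sums >= 1], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Phantom ground truth
#'
#' Per-voxel ground truth emitted alongside a generated phantom: the true
#' pool amplitude maps, the true B0 shift field, the tissue label map
#' (0 = background, 1 = WM, 2 = GM, 3 = tumor) and the noiseless Z-volume.
#'
#' @slot poolAmplitudes named list of 3-D arrays (`water`, `mt`, `apt`,
#'   `noe`), true amplitude per voxel.
#' @slot b0ShiftMap 3-D array of true B0 offsets, ppm.
#' @slot labelMap 3-D integer array of tissue labels.
#' @slot zNoiseless 4-D array of noise-free Z-spectra on the schedule.
#' @export
setClass("PhantomTruth",
  representation(
    poolAmplitudes = "list",
    b0ShiftMap = "array",
    labelMap = "array",
    zNoiseless = "array"
  )
)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "OffsetSchedule", function(object) {
  o <- object@offsets
  cat(sprintf("OffsetSchedule: %d offsets, %.4g to %.4g ppm\n",
              length(o), min(o), max(o)))
  cat(sprintf("  normalization at %g ppm (%d leading image(s) discarded)\n",
              object@normalizationOffset, object@nDiscardLeading))
})

setMethod("show", "SaturationTrain", function(object) {
  cat(sprintf(
    "SaturationTrain: %d pulses x (%g + %g) ms; total %.4g s, duty cycle %.3g",
    object@nPulses, object@pulseDuration, object@interpulseDelay,
    trainTotalDuration(object), trainDutyCycle(object)))
  if (is.finite(object@rmsB1)) cat(sprintf("; RMS B1 %g uT", object@rmsB1))
  cat("\n")
})

setMethod("show", "ZSpectrumVolume", function(object) {
  d <- dim(object@z)
  cat(sprintf("ZSpectrumVolume: %d x %d x %d voxels, %d offsets; %d masked voxels\n",
              d[1], d[2], d[3], d[4], sum(object@mask)))
})

setMethod("show", "RawCestSeries", function(object) {
  d <- dim(object@volumes)
  cat(sprintf("RawCestSeries: %d x %d x %d voxels, %d saturated volumes + S0\n",
              d[1], d[2], d[3], d[4]))
})

setMethod("show", "TwoPoolFit", function(object) {
  if (!object@converged) {
    cat("TwoPoolFit: not converged (sentinel)\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "TwoPoolFit: water A=%.4g L=%.4g d=%.4g | MT A=%.4g L=%.4g d=%.4g | b=%.4g\n",
    object@water@amplitude, object@water@width, object@water@center,
    object@mt@amplitude, object@mt@width, object@mt@center, object@baseline))
  cat(sprintf("  residual RMS %.3g over %d offsets\n",
              object@residualRms, object@nOffsetsUsed))
})

setMethod("show", "TwoPoolFitField", function(object) {
  n <- sum(object@mask)
  cat(sprintf("TwoPoolFitField: %s grid, %d fitted voxels, %.1f%% converged\n",
              paste(dim(object@mask), collapse = " x "), n,
              if (n) 100 * sum(object@converged, na.rm = TRUE) / n else 0))
})

setMethod("show", "CorrectedSpectra", function(object) {
  cat(sprintf(
    "CorrectedSpectra: %d voxels on a %d-point grid [%g, %g] ppm (0.1 ppm)\n",
    nrow(object@zCorrected), length(object@grid),
    min(object@grid), max(object@grid)))
})

setMethod("show", "MetricMap", function(object) {
  v <- object@values[is.finite(object@values)]
  cat(sprintf("MetricMap '%s'%s%s: %s grid, %d finite voxels",
              object@metricName,
              if (is.finite(object@offset))
                sprintf(" at %+g ppm", object@offset) else "",
              if (nzchar(object@b1Label))
                sprintf(" [%s]", object@b1Label) else "",
              paste(dim(object@values), collapse = " x "), length(v)))
  if (length(v)) cat(sprintf(", range [%.3g, %.3g]", min(v), max(v)))
  cat("\n")
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet: tumor %d, NAWM %d, NAGM %d voxels\n",
              sum(object@tumor), sum(object@nawm), sum(object@nagm)))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %s grid, tumor radius %g vox, conditions: %s\n",
    paste(object@gridShape, collapse = " x "), object@tumorRadius,
    paste(names(object@tissueTables), collapse = ", ")))
  cat(sprintf("  noise sigma %g, B0 field coef (%s) ppm, seed %d\n",
              object@noiseSigma, paste(object@b0Coef, collapse = ", "),
              object@seed))
})
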