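#' Default per-tissue pool table for one saturation-power condition
#'
#' Synthetic defaults (not measurements) for the four saturation pools —
#' water direct saturation, broad semi-solid MT, APT at +3.5 ppm (FWHM
#' 1 ppm), NOE at -3.5 ppm (FWHM 3 ppm) — in white matter, grey matter and
#' tumor. Under the `"1.5uT"` condition the tumor APT amplitude (0.04)
#' exceeds WM (0.02) and the tumor NOE amplitude (0.03) lies below WM
#' (0.05), so the pipeline should report a positive tumor-vs-NAWM APT
#' contrast and a negative NOE contrast. Under `"0.5uT"` the water/MT
#' background and the CEST amplitudes are scaled down, mimicking weaker
#' saturation labeling at lower power.
#'
#' @param b1Label `"1.5uT"` or `"0.5uT"`.
#' @return a data frame with columns `tissue`, `pool`, `A`, `L`, `delta`.
#' @export
defaultTissueTable <- function(b1Label = "1.5uT") {
  base <- rbind(
    data.frame(tissue = "wm",
               pool = c("water", "mt", "apt", "noe"),
               A = c(0.78, 0.12, 0.020, 0.050),
               L = c(1.4, 35, 1.0, 3.0),
               delta = c(0, 0, 3.5, -3.5)),
    data.frame(tissue = "gm",
               pool = c("water", "mt", "apt", "noe"),
               A = c(0.76, 0.08, 0.025, 0.040),
               L = c(1.6, 35, 1.0, 3.0),
               delta = c(0, 0, 3.5, -3.5)),
    data.frame(tissue = "tumor",
               pool = c("water", "mt", "apt", "noe"),
               A = c(0.80, 0.06, 0.040, 0.030),
               L = c(1.5, 35, 1.0, 3.0),
               delta = c(0, 0, 3.5, -3.5)))
  mult <- switch(b1Label,
    "1.5uT" = c(water = 1, mt = 1, apt = 1, noe = 1),
    "0.5uT" = c(water = 0.8, mt = 0.6, apt = 0.5, noe = 0.9),
    stop("unknown B1 condition label: ", b1Label))
  base$A <- base$A * mult[base$pool]
  rownames(base) <- NULL
  base
}

#' Construct a phantom configuration
#'
#' @param gridShape 3-D grid in voxels; default `c(32, 32, 8)`.
#' @param tumorRadius tumor sphere radius, voxels; default 5.
#' @param tumorCenter sphere center; default in the first-axis lower
#'   hemisphere at mid-depth.
#' @param tissueTables named list of pool tables per condition label;
#'   default the two [defaultTissueTable()] conditions.
#' @param b0Coef linear B0 field coefficients `(c0, cx, cy, cz)` in ppm
#'   over \[-1, 1\]-normalized coordinates; default a +/-0.3 ppm ramp
#'   along the first axis.
#' @param noiseSigma additive Gaussian noise SD on normalized signal;
#'   default 0 (noiseless).
#' @param s0Level S0 image intensity, scanner units; default 1000.
#' @param seed integer seed; default 1.
#' @return a validated [PhantomConfig-class].
#' @export
phantomConfig <- function(gridShape = c(32L, 32L, 8L),
                          tumorRadius = 5,
                          tumorCenter = NULL,
                          tissueTables = list(
                            "1.5uT" = defaultTissueTable("1.5uT"),
                            "0.5uT" = defaultTissueTable("0.5uT")),
                          b0Coef = c(0, 0.3, 0, 0),
                          noiseSigma = 0,
                          s0Level = 1000,
                          seed = 1L) {
  gridShape <- as.integer(gridShape)
  if (is.null(tumorCenter))
    tumorCenter <- c(round(gridShape[1] * 0.3), gridShape[2] / 2 + 0.5,
                     gridShape[3] / 2 + 0.5)
  new("PhantomConfig", gridShape = gridShape,
      tumorRadius = as.numeric(tumorRadius),
      tumorCenter = as.numeric(tumorCenter),
      tissueTables = tissueTables,
      b0Coef = as.numeric(b0Coef),
      noiseSigma = as.numeric(noiseSigma),
      s0Level = as.numeric(s0Level),
      seed = as.integer(seed))
}

# tissue label map: 0 background, 1 WM, 2 GM shell, 3 tumor sphere
.phantomLabels <- function(config) {
  d <- config@gridShape
  cx <- (d + 1) / 2
  ax <- d / 2
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  rho <- sqrt(((co$x - cx[1]) / ax[1])^2 + ((co$y - cx[2]) / ax[2])^2 +
              ((co$z - cx[3]) / ax[3])^2)
  lab <- integer(nrow(co))
  lab[rho <= 0.95] <- 2L              # GM shell: outer brain layer
  lab[rho <= 0.75] <- 1L              # WM core
  tc <- config@tumorCenter
  rt <- sqrt((co$x - tc[1])^2 + (co$y - tc[2])^2 + (co$z - tc[3])^2)
  sphere <- rt <= config@tumorRadius
  lab[sphere & lab > 0L] <- 3L        # tumor only inside the brain
  array(lab, d)
}

# smooth linear B0 field in ppm over [-1, 1] normalized coordinates
.phantomB0 <- function(config) {
  d <- config@gridShape
  nc <- function(i, n) if (n > 1) 2 * (i - 1) / (n - 1) - 1 else 0
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  b <- config@b0Coef
  array(b[1] + b[2] * nc(co$x, d[1]) + b[3] * nc(co$y, d[2]) +
        b[4] * nc(co$z, d[3]), d)
}

#' Generate a synthetic multi-pool CEST phantom
#'
#' Builds a 4-D raw CEST series with known ground truth. Geometry: an
#' ellipsoidal brain of white matter with a grey-matter shell and a
#' spherical tumor in the first-axis lower hemisphere. Per voxel, the
#' noiseless Z-spectrum is the multi-pool Lorentzian forward model
#' \deqn{Z(\Delta\omega) = 1 - \sum_{pools} A_p
#'   \mathcal{L}_p(\Delta\omega - \beta(v))}
#' evaluated on the schedule, where \eqn{\beta(v)} is the smooth B0 field.
#' Raw volumes are `s0Level * (Z + noise)` and the S0 image is
#' `s0Level * (1 + noise)` with i.i.d. Gaussian noise of SD `noiseSigma`.
#' The NAWM and NAGM reference masks are restricted to the first-axis
#' hemisphere opposite the tumor.
#'
#' @param config a [PhantomConfig-class].
#' @param schedule an [OffsetSchedule-class]; default
#'   [buildDefaultSchedule()].
#' @param condition which tissue-table condition label to simulate;
#'   default the first.
#' @return a list with elements `raw` ([RawCestSeries-class]), `rois`
#'   ([RoiSet-class]), `truth` ([PhantomTruth-class]) and `mask` (the 3-D
#'   logical brain mask).
#' @examples
#' ph <- generatePhantom(phantomConfig(gridShape = c(12, 12, 4)))
#' ph$rois
#' @export
generatePhantom <- function(config, schedule = buildDefaultSchedule(),
                            condition = names(config@tissueTables)[1]) {
  stopifnot(is(config, "PhantomConfig"), is(schedule, "OffsetSchedule"))
  validObject(config)
  tab <- config@tissueTables[[condition]]
  if (is.null(tab)) stop("unknown condition label: ", condition)
  d <- config@gridShape
  so <- schedule@offsets
  nOff <- length(so)
  lab <- .phantomLabels(config)
  beta <- .phantomB0(config)
  tissues <- c("wm", "gm", "tumor")
  poolNames <- c("water", "mt", "apt", "noe")

  amp <- lapply(poolNames, function(p) array(0, d))
  names(amp) <- poolNames
  zTrue <- array(NA_real_, c(d, nOff))
  nvox <- prod(d)
  for (ti in seq_along(tissues)) {
    vox <- which(lab == ti)
    if (!length(vox)) next
    rows <- tab[tab$tissue == tissues[ti], ]
    for (p in poolNames)
      amp[[p]][vox] <- rows$A[rows$pool == p]
    # spectra vary only through beta within a tissue: evaluate per voxel
    for (v in vox) {
      dwEff <- so - beta[v]
      zv <- rep(1, nOff)
      for (r in seq_len(nrow(rows)))
        zv <- zv - .lor(rows$A[r], rows$L[r], rows$delta[r], dwEff)
      zTrue[v + (seq_len(nOff) - 1L) * nvox] <- zv
    }
  }
  mask <- lab > 0L
  zTrue[.maskIdx4(!mask, nOff)] <- NA_real_

  set.seed(config@seed)
  zNoisy <- zTrue
  if (config@noiseSigma > 0)
    zNoisy <- zTrue + array(stats::rnorm(length(zTrue), 0,
                                         config@noiseSigma), dim(zTrue))
  volumes <- config@s0Level * zNoisy
  volumes[is.na(volumes)] <- 0
  s0 <- array(config@s0Level, d)
  if (config@noiseSigma > 0)
    s0 <- s0 * (1 + array(stats::rnorm(nvox, 0, config@noiseSigma), d))

  hemisphereOpp <- array(FALSE, d)
  hemisphereOpp[(seq_len(d[1]) > d[1] / 2), , ] <- TRUE
  rois <- RoiSet(tumor = lab == 3L,
                 nawm = lab == 1L & hemisphereOpp,
                 nagm = lab == 2L & hemisphereOpp)
  truth <- new("PhantomTruth", poolAmplitudes = amp, b0ShiftMap = beta,
               labelMap = lab, zNoiseless = zTrue)
  list(raw = RawCestSeries(volumes, schedule, s0),
       rois = rois, truth = truth, mask = mask)
}

#' @rdname labelMap
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' Phantom truth accessors
#'
#' @param x a [PhantomTruth-class].
#' @return `labelMap()` the 3-D tissue label array; `trueAmplitude()` the
#'   3-D true amplitude array of one pool; `trueB0()` the true B0 field.
#' @export
setMethod("labelMap", "PhantomTruth", function(x) x@labelMap)

#' @rdname labelMap
#' @param pool one of `"water"`, `"mt"`, `"apt"`, `"noe"`.
#' @export
trueAmplitude <- function(x, pool) x@poolAmplitudes[[pool]]

#' @rdname labelMap
#' @export
trueB0 <- function(x) x@b0ShiftMap
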