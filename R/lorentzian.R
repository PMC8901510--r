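#' Construct a Lorentzian pool
#'
#' @param amplitude peak amplitude, dimensionless, >= 0.
#' @param width full width at half maximum, ppm, > 0.
#' @param center center frequency, ppm.
#' @return a [LorentzianPool-class].
#' @export
LorentzianPool <- function(amplitude, width, center) {
  new("LorentzianPool", amplitude = as.numeric(amplitude),
      width = as.numeric(width), center = as.numeric(center))
}

#' Evaluate a Lorentzian line
#'
#' \deqn{A \frac{L^2/4}{L^2/4 + (\Delta\omega - \delta)^2}}
#' where `L` is the FWHM: the value at the center equals the amplitude and
#' falls to half amplitude at `center +/- L/2`.
#'
#' @param pool a [LorentzianPool-class].
#' @param dw frequency offset(s), ppm; vectorized.
#' @return dimensionless value(s), same length as `dw`.
#' @examples
#' p <- LorentzianPool(0.8, 2, 0)
#' lorentzianValue(p, c(0, 1, -1))  # 0.8, 0.4, 0.4
#' @export
lorentzianValue <- function(pool, dw) {
  stopifnot(is(pool, "LorentzianPool"))
  .lor(pool@amplitude, pool@width, pool@center, dw)
}

.lor <- function(A, L, d, dw) {
  u <- L^2 / 4
  A * u / (u + (dw - d)^2)
}

#' Two-pool reference Z-spectrum value
#'
#' Evaluates the water + MT background model
#' \eqn{Z_{ref}(\Delta\omega) = 1 - A_w \mathcal{L}_w(\Delta\omega)
#' - A_{MT} \mathcal{L}_{MT}(\Delta\omega) + b}.
#'
#' @param fit a [TwoPoolFit-class].
#' @param dw offset(s) in ppm; vectorized.
#' @return dimensionless Z_ref value(s).
#' @export
zrefValue <- function(fit, dw) {
  stopifnot(is(fit, "TwoPoolFit"))
  1 - lorentzianValue(fit@water, dw) - lorentzianValue(fit@mt, dw) +
    fit@baseline
}

.zrefP <- function(p, dw) {
  # p = (aWater, lWater, dWater, aMt, lMt, dMt, b)
  1 - .lor(p[1], p[2], p[3], dw) - .lor(p[4], p[5], p[6], dw) + p[7]
}

#' Default background-fit offset subsets
#'
#' Direct saturation is constrained at 0, +/-0.25, +/-0.5 and +/-1 ppm;
#' the broad MT pool at +/-100, +/-50, +/-40, +/-30, +/-20, +/-10, +/-9.5,
#' +/-9 and +/-8.5 ppm. Offsets carrying APT/NOE/amine signal are excluded
#' so the fit captures only the background.
#'
#' @param dsOffsets,mtOffsets override either subset (ppm).
#' @return a [FitSubsets-class].
#' @export
defaultFitSubsets <- function(
    dsOffsets = c(-1, -0.5, -0.25, 0, 0.25, 0.5, 1),
    mtOffsets = c(-100, -50, -40, -30, -20, -10, -9.5, -9, -8.5,
                  8.5, 9, 9.5, 10, 20, 30, 40, 50, 100)) {
  new("FitSubsets", dsOffsets = as.numeric(dsOffsets),
      mtOffsets = as.numeric(mtOffsets))
}

#' Two-pool fit configuration
#'
#' Starting values, box bounds and solver controls for the seven-parameter
#' background fit, in the order `aWater, lWater, dWater, aMt, lMt, dMt, b`
#' (amplitudes dimensionless, widths and centers in ppm). Defaults are
#' generic 3 T ranges: the water line starts at 0.8 amplitude / 1.5 ppm
#' FWHM, the MT line at 0.1 / 40 ppm; water center bounded to +/-1 ppm, MT
#' center to +/-4 ppm, baseline to +/-0.2.
#'
#' @param init,lower,upper numeric length-7 vectors.
#' @param ftol relative tolerance on the cost; default 1e-8.
#' @param maxIter maximum solver iterations; default 500.
#' @return a list with class `"twoPoolFitConfig"`.
#' @export
fitConfig <- function(
    init  = c(aWater = 0.8, lWater = 1.5, dWater = 0,
              aMt = 0.1, lMt = 40, dMt = 0, b = 0),
    lower = c(0, 0.3, -1, 0, 10, -4, -0.2),
    upper = c(1, 10, 1, 1, 300, 4, 0.2),
    ftol = 1e-8, maxIter = 500L) {
  stopifnot(length(init) == 7L, length(lower) == 7L, length(upper) == 7L,
            all(lower <= upper), all(init >= lower), all(init <= upper))
  structure(list(init = stats::setNames(as.numeric(init), .PARAM_NAMES),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 ftol = ftol, maxIter = as.integer(maxIter)),
            class = "twoPoolFitConfig")
}

# analytic Jacobian of the residual (model - data) wrt the 7 parameters
.zrefJac <- function(p, dw) {
  J <- matrix(0, length(dw), 7L)
  for (pool in 0:1) {
    A <- p[1 + 3 * pool]; L <- p[2 + 3 * pool]; d <- p[3 + 3 * pool]
    u <- L^2 / 4
    t <- (dw - d)^2
    den <- (u + t)^2
    J[, 1 + 3 * pool] <- -u / (u + t)
    J[, 2 + 3 * pool] <- -A * (L / 2) * t / den
    J[, 3 + 3 * pool] <- -A * 2 * u * (dw - d) / den
  }
  J[, 7L] <- 1
  J
}

# match subset offsets against schedule offsets within 0.01 ppm;
# errors if any subset entry is absent or ambiguous
.subsetIndices <- function(schedOffsets, subsets) {
  want <- c(subsets@dsOffsets, subsets@mtOffsets)
  idx <- vapply(want, function(w) {
    hit <- which(abs(schedOffsets - w) <= 0.01 + 1e-12)
    if (length(hit) != 1L)
      stop(sprintf(
        "fit subset offset %g ppm %s in the schedule (0.01 ppm match)",
        w, if (length(hit)) "is ambiguous" else "is missing"))
    hit
  }, integer(1))
  sort(idx)
}

.sentinelFit <- function(nUsed = 0L) {
  new("TwoPoolFit",
      water = LorentzianPool(0, 1, 0), mt = LorentzianPool(0, 1, 0),
      baseline = NA_real_, residualRms = NA_real_, converged = FALSE,
      nOffsetsUsed = as.integer(nUsed))
}

# core solver on pre-extracted (dw, z) pairs; returns param vector + diag
.fitCore <- function(dw, z, config) {
  res <- try(minpack.lm::nls.lm(
    par = config$init,
    lower = config$lower, upper = config$upper,
    fn = function(p) .zrefP(p, dw) - z,
    jac = function(p) .zrefJac(p, dw),
    control = minpack.lm::nls.lm.control(
      ftol = config$ftol, ptol = config$ftol, gtol = 0,
      maxiter = config$maxIter)), silent = TRUE)
  if (inherits(res, "try-error"))
    return(list(par = rep(NA_real_, 7L), rms = NA_real_, ok = FALSE))
  list(par = unname(res$par),
       rms = sqrt(mean(res$fvec^2)),
       ok = res$info %in% 1:4)
}

#' Fit the two-pool background model to one Z-spectrum
#'
#' Joint nonlinear least-squares fit (Levenberg-Marquardt with box
#' bounds and analytic Jacobian) of the seven parameters of the water + MT
#' model to the Z values at the background offset subsets. Offsets outside
#' the subsets never enter the fit. A voxel whose subset values are not
#' finite yields a sentinel fit with `converged = FALSE` rather than an
#' error.
#'
#' @param z numeric Z values, one per schedule offset.
#' @param schedOffsets ppm offsets matching `z` (or an
#'   [OffsetSchedule-class]).
#' @param subsets a [FitSubsets-class]; default [defaultFitSubsets()].
#' @param config a [fitConfig()] list.
#' @return a [TwoPoolFit-class].
#' @examples
#' sched <- buildDefaultSchedule()
#' truth <- TwoPoolFit(LorentzianPool(0.85, 1.4, 0.05),
#'                     LorentzianPool(0.10, 30, 0), 0)
#' fit <- fitTwoPool(zrefValue(truth, offsets(sched)), sched)
#' fit@water@amplitude  # ~0.85
#' @export
fitTwoPool <- function(z, schedOffsets, subsets = defaultFitSubsets(),
                       config = fitConfig()) {
  if (is(schedOffsets, "OffsetSchedule")) schedOffsets <- schedOffsets@offsets
  stopifnot(length(z) == length(schedOffsets))
  validObject(subsets)
  idx <- .subsetIndices(schedOffsets, subsets)
  if (length(idx) < 8L)
    stop("at least 8 background offsets are required for a 7-parameter fit")
  dw <- schedOffsets[idx]
  zi <- z[idx]
  if (anyNA(zi) || !all(is.finite(zi))) return(.sentinelFit(length(idx)))
  r <- .fitCore(dw, zi, config)
  if (!r$ok || anyNA(r$par)) return(.sentinelFit(length(idx)))
  TwoPoolFit(LorentzianPool(r$par[1], r$par[2], r$par[3]),
             LorentzianPool(r$par[4], r$par[5], r$par[6]),
             r$par[7], residualRms = r$rms, converged = TRUE,
             nOffsetsUsed = length(idx))
}

#' Construct a two-pool fit by hand
#'
#' Mostly useful for forward simulation and testing; [fitTwoPool()] is the
#' estimation entry point.
#'
#' @param water,mt [LorentzianPool-class] objects.
#' @param baseline constant baseline b.
#' @param residualRms,converged,nOffsetsUsed optional diagnostics.
#' @return a [TwoPoolFit-class].
#' @export
TwoPoolFit <- function(water, mt, baseline = 0, residualRms = 0,
                       converged = TRUE, nOffsetsUsed = 0L) {
  new("TwoPoolFit", water = water, mt = mt,
      baseline = as.numeric(baseline), residualRms = as.numeric(residualRms),
      converged = converged, nOffsetsUsed = as.integer(nOffsetsUsed))
}

#' Fit the background model over a masked volume
#'
#' Runs [fitTwoPool()] independently for every masked voxel and collects
#' the results as parameter maps. Voxels with non-finite subset values (or
#' solver failure) become sentinel voxels: `converged = FALSE`, `NA`
#' parameters. The convergence fraction is reported via `message()`.
#'
#' @param zvol a [ZSpectrumVolume-class].
#' @param subsets a [FitSubsets-class]; default [defaultFitSubsets()].
#' @param config a [fitConfig()] list.
#' @return a [TwoPoolFitField-class].
#' @export
fitVolume <- function(zvol, subsets = defaultFitSubsets(),
                      config = fitConfig()) {
  stopifnot(is(zvol, "ZSpectrumVolume"))
  validObject(subsets)
  so <- zvol@schedule@offsets
  idx <- .subsetIndices(so, subsets)
  dw <- so[idx]
  d3 <- dim(zvol@z)[1:3]
  nvox <- prod(d3)
  params <- array(NA_real_, c(d3, 7L))
  rms <- array(NA_real_, d3)
  conv <- array(FALSE, d3)
  vox <- which(zvol@mask)
  zmat <- matrix(zvol@z, nrow = nvox)[vox, idx, drop = FALSE]
  pstep <- nvox  # stride between parameter planes
  for (r in seq_along(vox)) {
    zi <- zmat[r, ]
    if (anyNA(zi) || !all(is.finite(zi))) next
    f <- .fitCore(dw, zi, config)
    if (!f$ok || anyNA(f$par)) next
    params[vox[r] + (0:6) * pstep] <- f$par
    rms[vox[r]] <- f$rms
    conv[vox[r]] <- TRUE
  }
  n <- length(vox)
  message(sprintf("fitVolume: %d/%d voxels converged (%.1f%%)",
                  sum(conv), n, if (n) 100 * sum(conv) / n else 0))
  new("TwoPoolFitField", params = params, residualRms = rms,
      converged = conv, mask = zvol@mask,
      nOffsetsUsed = length(idx))
}

#' @rdname fitParam
#' @export
setGeneric("fitParam", function(x, name) standardGeneric("fitParam"))

#' Extract one parameter map from a fit field
#'
#' @param x a [TwoPoolFitField-class].
#' @param name one of `"aWater"`, `"lWater"`, `"dWater"`, `"aMt"`,
#'   `"lMt"`, `"dMt"`, `"b"`.
#' @return 3-D numeric array (`NA` at non-converged voxels).
#' @export
setMethod("fitParam", "TwoPoolFitField", function(x, name) {
  i <- match(name, .PARAM_NAMES)
  if (is.na(i)) stop("unknown parameter name: ", name)
  d <- dim(x@params)
  array(x@params[, , , i], d[1:3])
})

# single-voxel TwoPoolFit from a fit field (internal)
.fieldFitAt <- function(field, v) {
  p <- field@params[v + (0:6) * prod(dim(field@mask))]
  if (anyNA(p)) return(.sentinelFit(field@nOffsetsUsed))
  TwoPoolFit(LorentzianPool(p[1], p[2], p[3]),
             LorentzianPool(p[4], p[5], p[6]), p[7],
             residualRms = field@residualRms[v], converged = TRUE,
             nOffsetsUsed = field@nOffsetsUsed)
}
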