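#' Construct a raw CEST series
#'
#' @param volumes 4-D array of saturated volumes (x, y, z, offset index),
#'   leading normalization-offset dummies already discarded.
#' @param schedule an [OffsetSchedule-class] describing the fourth axis.
#' @param s0Volume 3-D array, the retained normalization image.
#' @return a [RawCestSeries-class].
#' @export
RawCestSeries <- function(volumes, schedule, s0Volume) {
  new("RawCestSeries", volumes = volumes, schedule = schedule,
      s0Volume = s0Volume)
}

#' Normalize a raw series into Z-spectra
#'
#' Computes \eqn{Z(\Delta\omega) = S_{sat}(\Delta\omega) / S_0} voxel-wise
#' for every masked voxel. Voxels outside the mask are set to `NA` and
#' skipped by every downstream operation. The mask must exclude voxels
#' with non-positive S0.
#'
#' @param raw a [RawCestSeries-class].
#' @param mask 3-D logical analysis mask.
#' @return a [ZSpectrumVolume-class].
#' @examples
#' sched <- OffsetSchedule(c(-1, 0, 1))
#' v <- array(1, c(2, 2, 1, 3)); s0 <- array(2, c(2, 2, 1))
#' zvol <- normalizeZSpectra(RawCestSeries(v, sched, s0),
#'                           array(TRUE, c(2, 2, 1)))
#' range(zvol@z)  # 0.5 everywhere
#' @export
normalizeZSpectra <- function(raw, mask) {
  stopifnot(is(raw, "RawCestSeries"))
  validObject(raw)
  d <- dim(raw@volumes)
  if (!is.logical(mask) || !all(dim(mask) == d[1:3]))
    stop("mask must be a 3-D logical array matching the series grid")
  nBad <- sum(raw@s0Volume[mask] <= 0, na.rm = TRUE) +
    sum(is.na(raw@s0Volume[mask]))
  if (nBad > 0)
    stop(sprintf("S0 <= 0 (or missing) inside the mask at %d voxel(s); %s",
                 nBad, "tighten the mask before normalizing"))
  nOff <- d[4L]
  z <- raw@volumes / as.vector(raw@s0Volume)  # recycles s0 over offset axis
  z[.maskIdx4(!mask, nOff)] <- NA_real_
  new("ZSpectrumVolume", z = z, schedule = raw@schedule, mask = mask)
}

# replicate-pad a matrix by r rows/cols on each side
.padReplicate <- function(m, r) {
  i <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  j <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[i, j, drop = FALSE]
}

# local box mean over a w x w window with replicate boundary handling
.boxMean <- function(m, w) {
  r <- (w - 1L) %/% 2L
  p <- .padReplicate(m, r)
  k <- rep(1 / w, w)
  cm <- apply(p, 2L, function(col) stats::filter(col, k, sides = 2))
  cm <- matrix(cm, nrow = nrow(p))[(r + 1L):(r + nrow(m)), , drop = FALSE]
  rm <- t(apply(cm, 1L, function(row) stats::filter(row, k, sides = 2)))
  if (nrow(m) == 1L) rm <- matrix(rm, nrow = 1L)
  rm[, (r + 1L):(r + ncol(m)), drop = FALSE]
}

#' 2-D adaptive noise-removal filter
#'
#' Locally adaptive (Wiener-style) denoising of one image slice. For each
#' pixel, the local mean \eqn{\mu} and variance \eqn{\sigma^2} are
#' estimated over a square window; the noise power \eqn{\nu} is estimated
#' as the mean of the local variances over the slice (unless supplied);
#' the output is
#' \deqn{\mu + \frac{\max(\sigma^2 - \nu, 0)}{\max(\sigma^2, \epsilon)}
#'   (x - \mu).}
#' Smooth regions are pulled toward their local mean while structured
#' regions (local variance above the noise floor) are preserved. Image
#' borders use replicate padding.
#'
#' @param image 2-D numeric matrix (no `NA`s).
#' @param windowSize odd window side length >= 3; default 3.
#' @param noisePower optional externally estimated noise power; default
#'   `NULL` estimates it from the slice.
#' @return the filtered matrix, same dimensions.
#' @examples
#' x <- matrix(rnorm(64, sd = 0.05), 8, 8) + 1
#' y <- adaptiveFilter2d(x)
#' var(as.vector(y)) <= var(as.vector(x))
#' @export
adaptiveFilter2d <- function(image, windowSize = 3L, noisePower = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (anyNA(image)) stop("image must not contain NA; mask upstream")
  w <- as.integer(windowSize)
  if (w < 3L || w %% 2L == 0L)
    stop("windowSize must be odd and >= 3")
  if (w > nrow(image) || w > ncol(image))
    stop(sprintf("window (%d) larger than image (%d x %d)",
                 w, nrow(image), ncol(image)))
  mu <- .boxMean(image, w)
  sigma2 <- pmax(.boxMean(image^2, w) - mu^2, 0)
  nu <- if (is.null(noisePower)) mean(sigma2) else noisePower
  gain <- pmax(sigma2 - nu, 0) / pmax(sigma2, .Machine$double.eps)
  mu + gain * (image - mu)
}

#' Filter a Z-spectrum volume slice-wise
#'
#' Applies [adaptiveFilter2d()] independently to every axial (x-y) slice of
#' every offset volume. Schedule and mask are unchanged. Unmasked (`NA`)
#' pixels are temporarily replaced by the slice's masked mean so the local
#' statistics are defined everywhere, then restored to `NA`; pixels within
#' half a window of the mask boundary therefore mix in that fill value.
#'
#' @param zvol a [ZSpectrumVolume-class].
#' @param windowSize odd filter window, default 3.
#' @return a filtered [ZSpectrumVolume-class].
#' @export
filterSeries <- function(zvol, windowSize = 3L) {
  stopifnot(is(zvol, "ZSpectrumVolume"))
  d <- dim(zvol@z)
  out <- zvol@z
  for (k in seq_len(d[3L])) {
    mk <- zvol@mask[, , k]
    if (!any(mk)) next
    for (i in seq_len(d[4L])) {
      sl <- zvol@z[, , k, i]
      fill <- mean(sl[mk])
      sl[!mk] <- fill
      f <- adaptiveFilter2d(sl, windowSize)
      f[!mk] <- NA_real_
      out[, , k, i] <- f
    }
  }
  new("ZSpectrumVolume", z = pmax(out, 0), schedule = zvol@schedule,
      mask = zvol@mask)
}
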