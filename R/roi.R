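#' Construct an ROI mask set
#'
#' @param tumor,nawm,nagm 3-D logical masks on the metric-map grid;
#'   pairwise disjoint. A mask may be all-`FALSE`.
#' @return a [RoiSet-class].
#' @export
RoiSet <- function(tumor, nawm, nagm) {
  new("RoiSet", tumor = tumor, nawm = nawm, nagm = nagm)
}

# accept a MetricMap or a bare 3-D array
.mapValues <- function(map) {
  if (is(map, "MetricMap")) map@values else map
}

#' ROI mean and standard deviation
#'
#' Mean and sample standard deviation (denominator n - 1) of the metric
#' over the valid (finite) voxels of the mask. Flagged (`NA`) voxels are
#' excluded and their count reported.
#'
#' @param map a [MetricMap-class] or 3-D numeric array.
#' @param mask 3-D logical ROI mask, nonempty after exclusions.
#' @return a list with `mean`, `sd`, `n` (valid voxels) and `nExcluded`.
#' @examples
#' m <- array(c(1, 3, NA, 2), c(4, 1, 1))
#' roiMeanStd(m, array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1)))
#' @export
roiMeanStd <- function(map, mask) {
  v <- .mapValues(map)[mask]
  ok <- is.finite(v)
  if (!any(ok))
    stop("ROI has no valid voxels after excluding flagged values")
  list(mean = mean(v[ok]),
       sd = stats::sd(v[ok]),
       n = sum(ok), nExcluded = sum(!ok))
}

#' Tissue contrast between two ROIs
#'
#' \eqn{TC = \overline{m}_{tumor} - \overline{m}_{ref}}: the difference of
#' ROI means of the metric.
#'
#' @param map a [MetricMap-class] or 3-D array.
#' @param tumor,reference 3-D logical masks.
#' @return the contrast, dimensionless.
#' @export
tissueContrast <- function(map, tumor, reference) {
  roiMeanStd(map, tumor)$mean - roiMeanStd(map, reference)$mean
}

#' Contrast-to-noise ratio between two ROIs
#'
#' \eqn{CNR = TC / \sqrt{sd_{tumor}^2 + sd_{ref}^2}} with sample standard
#' deviations. A zero pooled standard deviation yields `NA` (undefined),
#' never infinity.
#'
#' @inheritParams tissueContrast
#' @return the CNR, dimensionless, or `NA` if undefined.
#' @examples
#' m <- array(c(1, 3, 0, 2), c(4, 1, 1))
#' tum <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
#' ref <- array(c(FALSE, FALSE, TRUE, TRUE), c(4, 1, 1))
#' contrastToNoise(m, tum, ref)  # 0.5
#' @export
contrastToNoise <- function(map, tumor, reference) {
  a <- roiMeanStd(map, tumor)
  b <- roiMeanStd(map, reference)
  pooled <- sqrt(a$sd^2 + b$sd^2)
  if (!is.finite(pooled) || pooled == 0) return(NA_real_)
  (a$mean - b$mean) / pooled
}

#' Patient-specific heterogeneity thresholds
#'
#' Hyper/hypo-intensity thresholds derived from the reference tissue
#' (NAWM) distribution of the same metric:
#' `hyper = mean + 2 sd`, `hypo = mean - 2 sd`. A zero reference SD
#' collapses the band; the result carries `degenerate = TRUE` in that
#' case.
#'
#' @param map a [MetricMap-class] or 3-D array.
#' @param nawm 3-D logical reference mask.
#' @return list with `hyper`, `hypo` and `degenerate`.
#' @examples
#' heterogeneityThresholds(array(c(0.75, 1, 1.25), c(3, 1, 1)),
#'                         array(TRUE, c(3, 1, 1)))
#' @export
heterogeneityThresholds <- function(map, nawm) {
  s <- roiMeanStd(map, nawm)
  list(hyper = s$mean + 2 * s$sd,
       hypo = s$mean - 2 * s$sd,
       degenerate = s$sd == 0)
}

#' Hyper/hypo-intense tumor volume percentages
#'
#' Fractions of tumor voxels strictly above the hyper threshold and
#' strictly below the hypo threshold, as percentages. The denominator is
#' the full tumor voxel count, including flagged (`NA`) voxels; flagged
#' voxels are never counted in a numerator. Values exactly at a threshold
#' belong to neither class.
#'
#' @param map a [MetricMap-class] or 3-D array.
#' @param tumor 3-D logical tumor mask, nonempty.
#' @param thresholds list with `hyper` and `hypo` (from
#'   [heterogeneityThresholds()]).
#' @return list with `vpHyper` and `vpHypo`, percent in \[0, 100\].
#' @examples
#' m <- array(c(0.4, 0.6, 1.6, 1.0), c(4, 1, 1))
#' volumePercent(m, array(TRUE, c(4, 1, 1)),
#'               list(hyper = 1.5, hypo = 0.5))  # 25 / 25
#' @export
volumePercent <- function(map, tumor, thresholds) {
  v <- .mapValues(map)[tumor]
  n <- length(v)
  if (n == 0L) stop("tumor mask is empty")
  list(vpHyper = 100 * sum(v > thresholds$hyper, na.rm = TRUE) / n,
       vpHypo = 100 * sum(v < thresholds$hypo, na.rm = TRUE) / n)
}

#' Build the per-metric ROI report
#'
#' Assembles, for each metric map, the ROI means/SDs, tumor-vs-NAWM and
#' tumor-vs-NAGM tissue contrast and CNR, the NAWM-derived heterogeneity
#' thresholds of that same metric, and the tumor hyper/hypo volume
#' percentages, as a tidy data frame (one row per metric). An empty NAWM
#' or NAGM mask leaves the dependent columns `NA`.
#'
#' @param maps named list of [MetricMap-class] objects (or one map).
#' @param rois a [RoiSet-class].
#' @return a `data.frame`, one row per metric.
#' @export
buildRoiReport <- function(maps, rois) {
  stopifnot(is(rois, "RoiSet"))
  if (is(maps, "MetricMap")) maps <- list(maps)
  rows <- lapply(maps, function(map) {
    stopifnot(is(map, "MetricMap"))
    if (!all(dim(map@values) == dim(rois@tumor)))
      stop("metric map and ROI masks are on different voxel grids")
    tum <- if (any(rois@tumor)) roiMeanStd(map, rois@tumor) else NULL
    wm <- if (any(rois@nawm)) roiMeanStd(map, rois@nawm) else NULL
    gm <- if (any(rois@nagm)) roiMeanStd(map, rois@nagm) else NULL
    thr <- vp <- NULL
    if (!is.null(tum) && !is.null(wm)) {
      thr <- heterogeneityThresholds(map, rois@nawm)
      vp <- volumePercent(map, rois@tumor, thr)
    }
    g <- function(x, f) if (is.null(x)) NA_real_ else f(x)
    data.frame(
      metric = map@metricName,
      b1 = map@b1Label,
      offset_ppm = map@offset,
      mean_tumor = g(tum, function(s) s$mean),
      sd_tumor = g(tum, function(s) s$sd),
      n_tumor = if (is.null(tum)) NA_integer_ else tum$n,
      mean_nawm = g(wm, function(s) s$mean),
      sd_nawm = g(wm, function(s) s$sd),
      mean_nagm = g(gm, function(s) s$mean),
      sd_nagm = g(gm, function(s) s$sd),
      tc_tumor_nawm = if (is.null(tum) || is.null(wm)) NA_real_ else
        tum$mean - wm$mean,
      tc_tumor_nagm = if (is.null(tum) || is.null(gm)) NA_real_ else
        tum$mean - gm$mean,
      cnr_tumor_nawm = if (is.null(tum) || is.null(wm)) NA_real_ else
        contrastToNoise(map, rois@tumor, rois@nawm),
      cnr_tumor_nagm = if (is.null(tum) || is.null(gm)) NA_real_ else
        contrastToNoise(map, rois@tumor, rois@nagm),
      thresh_hyper = g(thr, function(t) t$hyper),
      thresh_hypo = g(thr, function(t) t$hypo),
      vp_hyper_percent = g(vp, function(v) v$vpHyper),
      vp_hypo_percent = g(vp, function(v) v$vpHypo),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
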