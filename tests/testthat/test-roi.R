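arr3 <- function(v) array(v, c(length(v), 1, 1))
mask3 <- function(i, n) { m <- array(FALSE, c(n, 1, 1)); m[i, 1, 1] <- TRUE; m }

test_that("ROI mean/sd use the sample convention and skip flagged voxels", {
  s <- roiMeanStd(arr3(c(2, 2, 2)), array(TRUE, c(3, 1, 1)))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 0)
  s <- roiMeanStd(arr3(c(1, 3)), array(TRUE, c(2, 1, 1)))
  expect_equal(s$sd, sqrt(2))
  s <- roiMeanStd(arr3(c(1, 3, NA)), array(TRUE, c(3, 1, 1)))
  expect_equal(s$mean, 2)
  expect_equal(s$n, 2L)
  expect_equal(s$nExcluded, 1L)
  expect_error(roiMeanStd(arr3(c(NA, NA)), array(TRUE, c(2, 1, 1))),
               "no valid voxels")
})

test_that("tissue contrast is the difference of ROI means, antisymmetric", {
  m <- arr3(c(1, 3, 0, 2))
  a <- mask3(1:2, 4); b <- mask3(3:4, 4)
  expect_equal(tissueContrast(m, a, b), 1)
  expect_equal(tissueContrast(m, b, a), -1)
  expect_equal(tissueContrast(m, a, a), 0)
})

test_that("CNR matches hand arithmetic and is scale invariant", {
  m <- arr3(c(1, 3, 0, 2))
  tum <- mask3(1:2, 4); ref <- mask3(3:4, 4)
  expect_equal(contrastToNoise(m, tum, ref), 0.5)
  expect_equal(contrastToNoise(arr3(10 * c(1, 3, 0, 2)), tum, ref), 0.5)
  # equal means give 0; zero pooled sd gives NA, not Inf
  expect_equal(contrastToNoise(arr3(c(1, 3, 3, 1)), tum, ref), 0)
  expect_true(is.na(contrastToNoise(arr3(c(2, 2, 1, 1)), tum, ref)))
})

test_that("thresholds are NAWM mean +/- 2 sd, degenerate at zero sd", {
  thr <- heterogeneityThresholds(arr3(c(0.75, 1, 1.25)),
                                 array(TRUE, c(3, 1, 1)))
  expect_equal(thr$hyper, 1 + 2 * 0.25)
  expect_equal(thr$hypo, 1 - 2 * 0.25)
  expect_false(thr$degenerate)
  flat <- heterogeneityThresholds(arr3(c(1, 1)), array(TRUE, c(2, 1, 1)))
  expect_equal(flat$hyper, flat$hypo)
  expect_true(flat$degenerate)
})

test_that("volume percentages count strict exceedances over all tumor voxels", {
  tum <- array(TRUE, c(4, 1, 1))
  vp <- volumePercent(arr3(c(0.4, 0.6, 1.6, 1.0)), tum,
                      list(hyper = 1.5, hypo = 0.5))
  expect_equal(vp$vpHyper, 25)
  expect_equal(vp$vpHypo, 25)
  # ties belong to neither class
  vp <- volumePercent(arr3(c(1.5, 0.5, 1.5, 0.5)), tum,
                      list(hyper = 1.5, hypo = 0.5))
  expect_equal(vp$vpHyper, 0)
  expect_equal(vp$vpHypo, 0)
  # flagged voxels inflate the denominator only
  vp <- volumePercent(arr3(c(2, NA, NA, NA)), tum,
                      list(hyper = 1.5, hypo = 0.5))
  expect_equal(vp$vpHyper, 25)
  vp <- volumePercent(arr3(rep(0, 4)), tum, list(hyper = 1.5, hypo = 0.5))
  expect_equal(vp$vpHypo, 100)
  expect_equal(vp$vpHyper, 0)
  expect_error(volumePercent(arr3(1), array(FALSE, c(1, 1, 1)),
                             list(hyper = 1, hypo = 0)), "empty")
})

test_that("threshold construction is equivariant under affine maps", {
  set.seed(17)
  n <- 60
  vals <- rnorm(n)
  tum <- mask3(1:20, n); wm <- mask3(21:n, n)
  base <- volumePercent(arr3(vals), tum,
                        heterogeneityThresholds(arr3(vals), wm))
  for (case in list(c(2, 0.5), c(0.1, -3))) {
    tv <- case[1] * vals + case[2]
    got <- volumePercent(arr3(tv), tum,
                         heterogeneityThresholds(arr3(tv), wm))
    expect_equal(got, base)
  }
})

test_that("vpHyper + vpHypo is at most 100, exactly 100 when band is empty", {
  set.seed(23)
  vals <- rnorm(50)
  tum <- array(TRUE, c(50, 1, 1))
  vp <- volumePercent(arr3(vals), tum, list(hyper = 0.5, hypo = -0.5))
  expect_lte(vp$vpHyper + vp$vpHypo, 100)
  vpAll <- volumePercent(arr3(vals), tum, list(hyper = 0, hypo = 0))
  expect_equal(vpAll$vpHyper + vpAll$vpHypo, 100)  # no voxel sits at 0 a.s.
})

test_that("the report assembles per-metric rows and tolerates empty NAGM", {
  d <- c(6, 6, 1)
  set.seed(31)
  vals <- array(rnorm(prod(d), 1, 0.1), d)
  tum <- array(FALSE, d); tum[1:2, 1:2, 1] <- TRUE
  wm <- array(FALSE, d); wm[4:6, 4:6, 1] <- TRUE
  vals[tum] <- vals[tum] + 1  # constructed hyperintensity
  map <- new("MetricMap", values = vals, metricName = "LD_APT",
             offset = 3.5, b1Label = "1.5uT")
  rois <- RoiSet(tum, wm, array(FALSE, d))
  rep <- buildRoiReport(list(LD_APT = map), rois)
  expect_equal(nrow(rep), 1L)
  expect_gt(rep$tc_tumor_nawm, 0)
  expect_true(is.na(rep$tc_tumor_nagm))
  expect_true(is.na(rep$mean_nagm))
  # report values equal brute-force recomputation from the masked values
  expect_equal(rep$mean_tumor, mean(vals[tum]))
  expect_equal(rep$sd_nawm, sd(vals[wm]))
  expect_equal(rep$cnr_tumor_nawm,
               (mean(vals[tum]) - mean(vals[wm])) /
                 sqrt(var(vals[tum]) + var(vals[wm])))
  expect_equal(rep$thresh_hyper, mean(vals[wm]) + 2 * sd(vals[wm]))
})

test_that("overlapping ROI masks are rejected", {
  d <- c(2, 2, 1)
  m <- array(TRUE, d)
  expect_error(RoiSet(m, m, array(FALSE, d)), "disjoint")
})
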