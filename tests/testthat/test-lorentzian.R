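test_that("the Lorentzian line has amplitude at center and FWHM semantics", {
  p <- LorentzianPool(0.8, 2, 0)
  expect_equal(lorentzianValue(p, 0), 0.8)
  expect_equal(lorentzianValue(p, c(-1, 1)), c(0.4, 0.4))  # half max at L/2
  expect_equal(lorentzianValue(LorentzianPool(0.1, 30, 0), 15), 0.05)
})

test_that("the reference model assembles pools and baseline as 1 - sums + b", {
  flat <- TwoPoolFit(LorentzianPool(0, 1, 0), LorentzianPool(0, 1, 0), 0)
  expect_equal(zrefValue(flat, c(-10, 0, 3.5)), rep(1, 3))
  waterOnly <- TwoPoolFit(LorentzianPool(0.8, 2, 0), LorentzianPool(0, 1, 0), 0)
  expect_equal(zrefValue(waterOnly, 0), 0.2)
  withB <- TwoPoolFit(LorentzianPool(0.8, 2, 0), LorentzianPool(0.1, 30, 0),
                      0.03)
  expect_equal(zrefValue(withB, 1e6), 1.03, tolerance = 1e-9)
})

test_that("the single-pool model is exactly symmetric about its center", {
  f <- TwoPoolFit(LorentzianPool(0.7, 1.8, 0.4), LorentzianPool(0, 1, 0), 0)
  x <- c(0.1, 0.5, 1.7, 9)
  expect_identical(zrefValue(f, 0.4 + x), zrefValue(f, 0.4 - x))
})

test_that("noiseless spectra round-trip through the fit", {
  sched <- buildDefaultSchedule()
  truth <- c(aWater = 0.85, lWater = 1.4, dWater = 0.05,
             aMt = 0.10, lMt = 30, dMt = 0, b = 0)
  z <- zrefValue(paramsToFit(truth), offsets(sched))
  fit <- fitTwoPool(z, sched)
  expect_true(fit@converged)
  expect_equal(fit@nOffsetsUsed, 25L)
  est <- fitParamsVector(fit)
  expect_lt(max(abs(est - truth)[c(1, 2, 4, 5)] / truth[c(1, 2, 4, 5)]), 1e-3)
  expect_lt(max(abs(est - truth)[c(3, 6, 7)]), 1e-4)  # near-zero params
  expect_lt(fit@residualRms, 1e-6)

  shifted <- truth; shifted["dWater"] <- 0.3
  fit2 <- fitTwoPool(zrefValue(paramsToFit(shifted), offsets(sched)), sched)
  expect_equal(fit2@water@center, 0.3, tolerance = 0.01)
})

test_that("random in-bounds parameter draws are identifiable (property)", {
  sched <- buildDefaultSchedule()
  set.seed(42)
  for (i in 1:20) {
    truth <- drawFitParams()
    fit <- fitTwoPool(zrefValue(paramsToFit(truth), offsets(sched)), sched)
    expect_true(fit@converged)
    relErr <- abs(fitParamsVector(fit) - truth) / abs(truth)
    expect_lt(max(relErr), 1e-3)
    expect_lt(fit@residualRms, 1e-6)
  }
})

test_that("a flat spectrum fits with vanishing amplitudes and baseline", {
  sched <- buildDefaultSchedule()
  fit <- fitTwoPool(rep(1, 51), sched)
  expect_true(fit@converged)
  expect_lt(fit@water@amplitude, 1e-6)
  expect_lt(fit@mt@amplitude, 1e-6)
  expect_lt(abs(fit@baseline), 1e-6)
})

test_that("missing subset offsets fail before fitting; bad values sentinel", {
  sparse <- OffsetSchedule(c(-3.5, 0, 3.5))
  expect_error(fitTwoPool(c(1, 0.3, 0.9), sparse), "missing")
  sched <- buildDefaultSchedule()
  z <- zrefValue(paramsToFit(drawFitParams()), offsets(sched))
  z[which(abs(offsets(sched)) < 0.1)] <- NA
  fit <- fitTwoPool(z, sched)
  expect_false(fit@converged)
  expect_true(is.na(fit@baseline))
})

test_that("volume fitting recovers a spatially varying MT amplitude map", {
  sched <- buildDefaultSchedule()
  d <- c(6, 6, 1)
  aMt <- array(seq(0.05, 0.15, length.out = prod(d)), d)
  z <- array(NA_real_, c(d, 51))
  for (v in seq_len(prod(d))) {
    f <- TwoPoolFit(LorentzianPool(0.8, 1.5, 0), LorentzianPool(aMt[v], 35, 0),
                    0)
    z[v + (seq_len(51) - 1) * prod(d)] <- zrefValue(f, offsets(sched))
  }
  mask <- array(TRUE, d)
  mask[1, 1, 1] <- FALSE
  zvol <- new("ZSpectrumVolume", z = z, schedule = sched, mask = mask)
  field <- suppressMessages(fitVolume(zvol))
  est <- fitParam(field, "aMt")
  expect_true(is.na(est[1, 1, 1]))  # unmasked voxel untouched
  ok <- !is.na(est)
  expect_gt(stats::cor(est[ok], aMt[ok]), 0.99)
  expect_lt(max(abs(est[ok] - aMt[ok])), 1e-4)
})

test_that("an all-false mask yields an empty fit field", {
  sched <- buildDefaultSchedule()
  d <- c(3, 3, 1)
  zvol <- new("ZSpectrumVolume",
              z = array(NA_real_, c(d, 51)), schedule = sched,
              mask = array(FALSE, d))
  field <- suppressMessages(fitVolume(zvol))
  expect_true(all(is.na(field@params)))
  expect_false(any(field@converged))
})
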