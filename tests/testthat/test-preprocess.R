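makeRaw <- function(volumes, s0, sched = NULL) {
  d <- dim(volumes)
  if (is.null(sched)) sched <- OffsetSchedule(seq_len(d[4]))
  RawCestSeries(volumes, sched, s0)
}

test_that("normalization divides each offset volume by S0", {
  d <- c(3, 3, 2)
  s0 <- array(2, d)
  vols <- array(0, c(d, 3))
  vols[, , , 1] <- 1.8; vols[, , , 2] <- 1.0; vols[, , , 3] <- 0.4
  zvol <- normalizeZSpectra(makeRaw(vols, s0), array(TRUE, d))
  expect_equal(unique(as.vector(zvol@z[, , , 1])), 0.9)
  expect_equal(unique(as.vector(zvol@z[, , , 2])), 0.5)
  expect_equal(unique(as.vector(zvol@z[, , , 3])), 0.2)
})

test_that("self-normalization gives Z = 1 and zero signal gives Z = 0", {
  d <- c(2, 2, 1)
  s0 <- array(runif(prod(d), 0.5, 2), d)
  vols <- array(rep(s0, 2), c(d, 2))
  vols[1, 1, 1, 2] <- 0
  zvol <- normalizeZSpectra(makeRaw(vols, s0), array(TRUE, d))
  expect_equal(as.vector(zvol@z[, , , 1]), rep(1, 4))
  expect_equal(zvol@z[1, 1, 1, 2], 0)
})

test_that("normalization is invariant to a common positive scaling", {
  d <- c(4, 4, 2)
  set.seed(11)
  s0 <- array(runif(prod(d), 0.5, 2), d)
  vols <- array(runif(prod(d) * 3, 0, 2), c(d, 3))
  mask <- array(TRUE, d)
  z1 <- normalizeZSpectra(makeRaw(vols, s0), mask)@z
  z2 <- normalizeZSpectra(makeRaw(vols * 7.5, s0 * 7.5), mask)@z
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("normalization validates shapes and S0 positivity inside the mask", {
  d <- c(3, 3, 1)
  vols <- array(1, c(d, 2))
  s0 <- array(1, d)
  s0[2, 2, 1] <- 0
  expect_error(normalizeZSpectra(makeRaw(vols, s0), array(TRUE, c(2, 2, 1))),
               "mask")
  expect_error(normalizeZSpectra(makeRaw(vols, s0), array(TRUE, d)),
               "1 voxel")
  mask <- array(TRUE, d)
  mask[2, 2, 1] <- FALSE  # excluding the bad voxel is fine
  zvol <- normalizeZSpectra(makeRaw(vols, s0), mask)
  expect_true(all(is.na(zvol@z[2, 2, 1, ])))
})

test_that("adaptive filter matches the per-pixel formula on a 5x5 oracle", {
  set.seed(3)
  x <- matrix(rnorm(25, mean = 1, sd = 0.1), 5, 5)
  got <- adaptiveFilter2d(x, 3L)

  # brute-force oracle: explicit loops, replicate padding
  pad <- rbind(x[1, , drop = FALSE], x, x[5, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, 5, drop = FALSE])
  mu <- s2 <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    win <- pad[i:(i + 2), j:(j + 2)]
    mu[i, j] <- mean(win)
    s2[i, j] <- mean(win^2) - mean(win)^2
  }
  nu <- mean(s2)
  want <- mu + pmax(s2 - nu, 0) / pmax(s2, .Machine$double.eps) * (x - mu)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("adaptive filter passes constants and shrinks pure noise", {
  cst <- matrix(3.7, 6, 6)
  expect_equal(adaptiveFilter2d(cst), cst, tolerance = 1e-12)
  set.seed(5)
  noise <- matrix(rnorm(400), 20, 20)
  filtered <- adaptiveFilter2d(noise)
  expect_lt(var(as.vector(filtered)), var(as.vector(noise)))
})

test_that("adaptive filter validates its window", {
  x <- matrix(0, 4, 4)
  expect_error(adaptiveFilter2d(x, 4L), "odd")
  expect_error(adaptiveFilter2d(x, 5L), "larger than image")
})

test_that("series filtering reduces noise and keeps shape and mask", {
  sched <- OffsetSchedule(c(-2, 0, 2))
  d <- c(10, 10, 2)
  truth <- array(rep(c(0.9, 0.5, 0.7), each = prod(d)), c(d, 3))
  set.seed(9)
  noisy <- truth + array(rnorm(length(truth), sd = 0.01), dim(truth))
  mask <- array(TRUE, d)
  zvol <- new("ZSpectrumVolume", z = noisy, schedule = sched, mask = mask)
  out <- filterSeries(zvol)
  expect_identical(dim(out@z), dim(noisy))
  expect_identical(out@mask, mask)
  rmsBefore <- sqrt(mean((noisy - truth)^2))
  rmsAfter <- sqrt(mean((out@z - truth)^2))
  expect_lt(rmsAfter, rmsBefore)
})

test_that("series filtering is exact on constant volumes (idempotent)", {
  sched <- OffsetSchedule(c(0, 1))
  d <- c(6, 6, 1)
  z <- array(0.8, c(d, 2))
  zvol <- new("ZSpectrumVolume", z = z, schedule = sched,
              mask = array(TRUE, d))
  once <- filterSeries(zvol)
  expect_equal(once@z, z, tolerance = 1e-14)
  expect_equal(filterSeries(once)@z, once@z, tolerance = 1e-14)
})
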