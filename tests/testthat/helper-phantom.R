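# Shared fixtures, built in code at test time.

# a small phantom configuration that keeps voxel-wise fitting fast
smallPhantomConfig <- function(noiseSigma = 0, seed = 1L, ...) {
  phantomConfig(gridShape = c(14L, 14L, 4L), tumorRadius = 3,
                noiseSigma = noiseSigma, seed = seed, ...)
}

# evaluate a multi-pool Z-spectrum directly from a pool table row set
# (independent forward oracle: plain arithmetic, no package model objects)
oracleSpectrum <- function(poolTable, dw, beta = 0) {
  z <- rep(1, length(dw))
  for (r in seq_len(nrow(poolTable))) {
    u <- poolTable$L[r]^2 / 4
    z <- z - poolTable$A[r] * u / (u + (dw - beta - poolTable$delta[r])^2)
  }
  z
}

# collect the 7 fitted parameters of a TwoPoolFit as a named vector
fitParamsVector <- function(fit) {
  c(aWater = fit@water@amplitude, lWater = fit@water@width,
    dWater = fit@water@center, aMt = fit@mt@amplitude,
    lMt = fit@mt@width, dMt = fit@mt@center, b = fit@baseline)
}

# draw one random parameter set well inside the default fit bounds
drawFitParams <- function() {
  c(aWater = runif(1, 0.6, 0.95),
    lWater = runif(1, 0.8, 3),
    dWater = sample(c(-1, 1), 1) * runif(1, 0.05, 0.3),
    aMt = runif(1, 0.02, 0.3),
    lMt = runif(1, 20, 100),
    dMt = sample(c(-1, 1), 1) * runif(1, 0.2, 2),
    b = sample(c(-1, 1), 1) * runif(1, 0.02, 0.05))
}

paramsToFit <- function(p) {
  TwoPoolFit(LorentzianPool(p[["aWater"]], p[["lWater"]], p[["dWater"]]),
             LorentzianPool(p[["aMt"]], p[["lMt"]], p[["dMt"]]),
             p[["b"]])
}

readVolFile <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  a[is.nan(a)] <- NA_real_
  a
}
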