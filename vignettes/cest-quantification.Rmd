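---
title: "Two-pool Lorentzian quantification of CEST Z-spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-pool Lorentzian quantification of CEST Z-spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestKit)
```

## The model

Chemical exchange saturation transfer (CEST) imaging detects dilute
exchangeable protons — amide protons of mobile proteins at +3.5 ppm
(APT), aliphatic protons coupled through the nuclear Overhauser effect at
−3.5 ppm (NOE) — by their attenuation of the water signal under
off-resonance saturation. The measured quantity is the Z-spectrum,
`Z(Δω) = S_sat(Δω)/S0`, where `S0` is acquired far off resonance
(−300 ppm here; two images are collected there and the first discarded
because the signal has not reached steady state).

At 3 T the individual CEST lines are broad and mixed, so instead of a
full multi-pool decomposition the package models only the *background*:
direct water saturation (DS) and the very broad semi-solid magnetization
transfer (MT) pool, each as a Lorentzian with amplitude `A`, full width
at half maximum `L` and center `δ`, plus a constant baseline `b`:

$$Z_{ref}(\Delta\omega) = 1 - A_w\,\mathcal{L}_w(\Delta\omega)
  - A_{MT}\,\mathcal{L}_{MT}(\Delta\omega) + b,\qquad
  \mathcal{L}(\Delta\omega) = \frac{L^2/4}{L^2/4 + (\Delta\omega-\delta)^2}.$$

The `L²/4` form makes `L` the FWHM. The seven parameters are estimated
jointly by bounded Levenberg–Marquardt least squares (`minpack.lm`, with
an analytic Jacobian) — the two offset subsets merely select which data
constrain the model, the model itself is one equation. Only
background-dominated offsets enter the fit: 0, ±0.25, ±0.5, ±1 ppm for
DS and ±8.5, ±9, ±9.5, ±10, ±20 … ±50, ±100 ppm for MT. Offsets carrying
APT/NOE/amine signal are deliberately excluded.

Saturation effects are then quantified against this background as the
Lorentzian difference `LD = Zref − Z` and the spillover-compensated
inverse metric `MTR_REX = 1/Z − 1/Zref`; for `Z, Zref` near 1 the two
agree to first order (`MTR_REX ≈ LD/(Z·Zref)`), and they always share a
sign for positive arguments.

## The sampling schedule

The default schedule (51 offsets) samples ±100 ppm; ±50 to ±20 in 10 ppm
steps; ±10 to ±5 and ±4 to ±1 in 0.5 ppm steps; and ±0.5 to 0 in
0.25 ppm steps. The 0.5 ppm step between 5 and 10 ppm is chosen so that
the MT fit subset (±8.5, ±9, ±9.5 ppm) exists in the schedule; the
schedule is fully configurable (`OffsetSchedule()`, JSON sidecars) for
other samplings. Saturation-train timing is pure bookkeeping:
`trainTotalDuration()` and `trainDutyCycle()` reproduce, e.g., 3.2 s and
50% for 80 pulses of 20 ms with 20 ms gaps.

## Pipeline stages and numerical choices

**Normalization.** `Z = S_sat/S0` per voxel inside an analysis mask;
voxels with non-positive `S0` must be excluded by the mask (validated
with a counted error). Outside the mask the missing-value marker is `NA`
and every downstream operation skips it.

**Adaptive filtering.** Each axial slice of each offset volume passes
through a locally adaptive Wiener-style filter: with local window mean
`μ` and variance `σ²` and slice-wide noise power `ν` (mean of local
variances), the output is `μ + max(σ²−ν,0)/max(σ²,ε)·(x−μ)`. The window
defaults to 3×3, the conventional choice for this filter. Filtering is
applied *after* normalization. Two consequences worth knowing: constant
regions pass through exactly, but pixels within half a window of a
tissue boundary (or of the mask edge, where the slice mean is used as
fill) are mixed with their neighbours. On a noiseless piecewise-constant
phantom this mixing — not any solver property — dominates the residual
error of downstream per-tissue summaries.

**Voxel-wise fitting.** Initialization `A_w=0.8, L_w=1.5, δ_w=0,
A_MT=0.1, L_MT=40, δ_MT=0, b=0`; bounds `A∈[0,1]`, `L_w∈[0.3,10]`,
`δ_w∈[−1,1]`, `L_MT∈[10,300]`, `δ_MT∈[−4,4]`, `b∈[−0.2,0.2]` (ppm where
applicable) — generic 3 T ranges, all configurable via `fitConfig()`.
`δ_MT` is left free within its bounds rather than tied to `δ_w`, and `b`
is signed, since neither constraint is forced by the model. Solver
tolerance is 1e−8 on the cost with at most 500 iterations;
non-convergence or non-finite inputs yield a flagged sentinel voxel,
never an error. On noiseless model spectra the seven parameters are
recovered to ~1e−13 relative error (the acceptance script measures this
over 100 random in-bounds draws; draws are kept away from zero and from
the bound edges so "relative error" is well defined and the claim is
about identifiability, not about active box constraints).

**B0 correction.** The per-voxel field offset is read off as the argmin
of the fitted background over a dense grid (±2 ppm at 0.001 ppm); for a
lone water pool this is exactly `δ_w`, and a broad off-center MT pool
pulls it only weakly. The measured `Z` and the point-wise `LD` are then
translated by that shift and linearly interpolated onto a fixed grid
(−100 to 100 ppm, 0.1 ppm spacing, built from integers so ±3.5 ppm are
exact grid points); beyond the sampled range the nearest measured value
is held. Both spectra are treated identically, so the corrected
reference is recoverable as `Zref = Z + LD` on the grid, and `MTR_REX`
is evaluated from the *window-averaged* corrected `Z` and `Zref` (the
closed ±0.2 ppm window holds exactly five grid points; endpoints are
included). Linear interpolation was chosen over cubic for monotonicity
at the sparse far-off offsets; we measured natural cubic splines on the
shifted-spectrum inversion problem and they bought no accuracy (see
Limitations), so the simpler rule is the default.

**Metrics and ROI statistics.** `MTR_REX` guards its reciprocals with
`ε = 1e−3`: near-fully-saturated voxels are flagged `NA` and counted,
never clipped, so ROI statistics are not biased by fabricated values.
ROI summaries use the sample standard deviation (n−1) throughout —
contrast-to-noise, thresholds and all. Heterogeneity thresholds
`mean(NAWM) ± 2·sd(NAWM)` are computed per subject *and per metric*
(thresholds always derive from the metric they classify); the
hyper/hypo volume percentages use strict inequalities, count flagged
voxels in the denominator only, and treat values exactly at a threshold
as belonging to neither class.

## The synthetic phantom

The generator emulates what the pipeline consumes, not how spectra arise
physically: per voxel, `Z(Δω) = 1 − Σ_p A_p 𝓛_p(Δω − β(v))` over four
pools (water, MT, APT with FWHM 1 ppm at +3.5, NOE with FWHM 3 ppm at
−3.5), a linear B0 field `β` spanning ±0.3 ppm, and optional additive
Gaussian noise on the normalized signal (high-SNR magnitude data are
near-Gaussian, and the analysis operates post-normalization; Rician
noise is deliberately out of scope). Saturation-power dependence is
phenomenological — per-pool amplitude multipliers per condition label —
because the pipeline under test is agnostic to how the spectra were
produced; no Bloch-McConnell simulation is attempted. Geometry is an
ellipsoidal white-matter brain with a grey-matter shell and a spherical
tumor; the NAWM/NAGM reference masks live in the hemisphere opposite
the tumor. The default grid is 32×32×8 voxels, which keeps a full
voxel-wise run (≈3700 fits) at a few seconds while exercising every
stage; tests use 14×14×4.

All pool amplitudes are synthetic defaults chosen for qualitative
realism, not measurements: under the "1.5uT" condition tumor APT (0.04)
exceeds WM APT (0.02) while tumor NOE (0.03) lies below WM NOE (0.05),
so a correct pipeline reports positive APT and negative NOE
tumor-vs-NAWM contrast; under "0.5uT" all CEST amplitudes scale down.
What passing phantom tests does *not* show: performance under realistic
anatomy, Rician noise, motion, B1 inhomogeneity, or exchange-rate
physics — none of which the generator models.

## Known limitations

Two quantitative limits of the method itself (not of the code) surface
on the phantom and are measured by `scripts/acceptance.R` rather than
hidden:

* **CEST contamination of the background fit.** The NOE line's broad
  wings (FWHM 3 ppm) reach both the DS subset and the ±8.5–10 ppm MT
  subset, biasing the fitted MT amplitude by roughly 3–7% depending on
  tissue; the APT line alone contributes only ~0.2–0.3%. The fitted maps
  still track spatial truth almost perfectly (r > 0.99), but absolute
  MT amplitudes inherit this background-model bias.
* **Line undersampling during B0 resampling.** With 0.5 ppm sampling
  around +3.5 ppm (and a 1 ppm gap between 4 and 5 ppm), a field shift
  that moves the narrow APT apex between sample points cannot be undone
  by any interpolation rule: the window-averaged LD_APT deviates by up
  to ~25% from its on-grid reference across shifts up to ±0.5 ppm (the
  B0 shift itself is recovered to ~0.001 ppm). Denser sampling around
  the resonances of interest is the only cure.

The pipeline deliberately omits MTR_asym, AREX/T1 compensation,
multi-pool (>2) fitting, super-Lorentzian MT line shapes, motion
correction, registration and segmentation; group-level inference
consumes the per-subject report produced here but is performed with
standard tests elsewhere.

## A complete run

```{r example, eval = FALSE}
ph   <- generatePhantom(phantomConfig(gridShape = c(14, 14, 4),
                                      tumorRadius = 3))
zvol <- filterSeries(normalizeZSpectra(ph$raw, ph$mask))
fits <- fitVolume(zvol)
maps <- extractMetricMaps(correctB0(zvol, fits), fits, b1Label = "1.5uT")
buildRoiReport(maps, ph$rois)
```

File-based runs (`runPipeline()`, or the CLI under `inst/scripts/`)
write NIfTI volumes for every intermediate, JSON sidecars for schedules
and fit configurations, a per-stage log, and a manifest with MD5
checksums; identically seeded runs are byte-identical, and running the
stages one by one reproduces the one-shot outputs exactly.
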