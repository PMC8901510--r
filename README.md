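# cestKit

Quantification of chemical exchange saturation transfer (CEST) MRI
Z-spectra at clinical field strength, built around two-pool Lorentzian
background fitting. The package targets researchers analysing pulsed-CEST
brain acquisitions — for example amide proton transfer (APT) and nuclear
Overhauser enhancement (NOE) imaging of glioma — who need a tested,
scriptable pipeline from raw saturated volumes to per-region tumor
heterogeneity statistics.

## The method

A CEST acquisition measures the normalized water signal

```
Z(Δω) = S_sat(Δω) / S0
```

at a schedule of saturation frequency offsets Δω (ppm relative to water).
After 2-D adaptive noise-removal filtering, the spectral *background* —
direct water saturation (DS) plus the broad semi-solid magnetization
transfer (MT) pool — is fitted voxel-wise with a two-pool Lorentzian model

```
Zref(Δω) = 1 − A_w · (L_w²/4) / (L_w²/4 + (Δω − δ_w)²)
             − A_MT · (L_MT²/4) / (L_MT²/4 + (Δω − δ_MT)²) + b
```

using only background-dominated offsets (0, ±0.25, ±0.5, ±1 ppm for DS;
±8.5 … ±10, ±20 … ±50, ±100 ppm for MT). The fit provides three things:

1. **B0 correction** — each voxel's spectrum is shifted by the frequency
   of the fitted minimum, resampled to a 0.1 ppm grid from −100 to
   100 ppm, and window-averaged over ±0.2 ppm;
2. **Lorentzian difference** `LD = Zref − Z`, isolating the saturation
   effects the background model excludes;
3. **Inverse magnetization transfer ratio** `MTR_REX = 1/Z − 1/Zref`,
   which additionally compensates spillover dilution.

APT (+3.5 ppm) and NOE (−3.5 ppm) maps of both metrics, plus the fitted
MT amplitude map, feed the region-of-interest statistics: tissue contrast
`TC = mean(tumor) − mean(reference)`, contrast-to-noise ratio
`CNR = TC / sqrt(sd_tumor² + sd_ref²)`, and patient-specific
heterogeneity thresholds `mean(NAWM) ± 2·sd(NAWM)` from which the
hyper-/hypo-intense tumor volume percentages are counted.

A multi-pool synthetic phantom generator (water + MT + APT + NOE pools,
smooth B0 field, optional Gaussian noise, two saturation-power
conditions) provides ground truth for every stage.

## Worked example

```r
library(cestKit)

ph   <- generatePhantom(phantomConfig(gridShape = c(14, 14, 4),
                                      tumorRadius = 3))
zvol <- filterSeries(normalizeZSpectra(ph$raw, ph$mask))
fits <- fitVolume(zvol)
#> fitVolume: 352/352 voxels converged (100.0%)
maps <- extractMetricMaps(correctB0(zvol, fits), fits, b1Label = "1.5uT")
rep  <- buildRoiReport(maps, ph$rois)
rep[rep$metric == "LD_APT",
    c("metric", "mean_tumor", "mean_nawm", "tc_tumor_nawm",
      "vp_hyper_percent")]
#>   metric mean_tumor  mean_nawm tc_tumor_nawm vp_hyper_percent
#> 1 LD_APT 0.03051222 0.01476841    0.01574381              100
```

The tumor's APT pool was simulated at twice the white-matter amplitude,
so the APT Lorentzian-difference map shows a positive tumor-vs-NAWM
tissue contrast of about 0.016 (window-averaged LD units) and every tumor
voxel exceeds the NAWM-derived hyperintensity threshold in this noiseless
toy run. The full pipeline, including NIfTI outputs and a checksummed
manifest, runs via `runPipeline(pipelineConfig(outDir))` or the CLI in
`inst/scripts/cest-pipeline.R` (subcommands `simulate`, `normalize`,
`fit`, `b0correct`, `maps`, `roistats`, `run-all`).

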