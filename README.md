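# breastCompRT

Automated breast-composition analysis on radiotherapy planning CT, and its
link to breast toxicity.

After breast-conserving surgery and radiotherapy (RT), late side effects —
pain, oedema, atrophy, induration — may depend not only on the dose but on
*what tissue* the dose lands in. The breast is mostly a two-tissue organ on
CT: fat (low Hounsfield units, around −110 HU) and fibroglandular tissue
(higher HU, around −50 HU and above). `breastCompRT` implements a pipeline
that characterises each patient's breast composition directly from the
planning CT, measures dose to the resulting substructures, and relates both
to ordinal toxicity grades:

1. **Skin cropping** — breast contours are cropped 5 mm from the body
   surface (exact anisotropic Euclidean distance transform), because
   superficial dose is unreliable in treatment planning systems.
2. **Global density classification** — three first-order intensity
   features per breast (median, IQR, uniformity `U = Σ p(i)²` over a
   25-HU histogram) are z-scored and k-means-clustered with k = 4 into
   BI-RADS-like classes: *fatty*, *scattered*, *heterogeneously dense*,
   *extremely dense*, named by ascending centroid median HU.
3. **Tissue segmentation** — per patient, a two-component Gaussian mixture
   is fitted by EM to the breast HU histogram inside a restricted window
   (default [−200, 100] HU, refined once per case to the fitted ±2 SD
   range). Tissue intervals are μ ± 2σ per component; overlapping voxels
   are classified as fat (the narrower, more distinct peak). Fat,
   fibroglandular and unclassified masks partition the breast exactly.
4. **Substructure dosimetry** — mean, maximum and uniformity of dose per
   structure, for physical dose and for EQD2 under the linear-quadratic
   model, `EQD2 = D·(d + α/β)/(2 + α/β)` with `d = D/n` and α/β = 1.7 Gy.
5. **Toxicity association** — clinician and patient grades (0–3) are
   merged by maximum severity; candidate composition/dose variables are
   screened for collinearity (|r| ≥ 0.9), then forward (and backward)
   AIC-stepwise proportional-odds ordinal regression is run around a fixed
   clinical baseline, per endpoint and timepoint.

Every stage is exercisable without clinical data through a synthetic
phantom/cohort generator with machine-readable ground truth (tissue masks,
dose fields, outcome-model coefficients).

## Worked example

```r
library(breastCompRT)

# a fatty-archetype phantom with known tissue ground truth
ph  <- generateBreastPhantom(phantomSpec("fatty"), seed = 2)
res <- classifyBreastTissue(ph$ct, ph$breast)
res$fit
#> Two-component Gaussian mixture (HU)
#>   fat:            weight 0.850, mean  -109.7, SD  4.72
#>   fibroglandular: weight 0.150, mean   -52.6, SD 11.18
#>   window [-120, -28] HU, n = 29050, logLik -102350.0, converged (11 iter)
res$segmentation
#> TissueSegmentation: fat 79.8%, fibroglandular 14.1%, unclassified 6.0%

# dose with a boost centred in fibroglandular tissue, and EQD2 metrics
dose <- generateDose(ph$breast, baseGy = 40.05, nFractions = 15,
                     boost = list(amplitudeGy = 8, sigmaMm = 12),
                     boostIn = ph$fgTruth)
substructureDoseReport(dose, res$segmentation, ph$breast,
                       FractionationScheme(15, alphaBeta = 1.7))
#>        structure dose_kind n_voxels  mean_gy   max_gy uniformity
#> 1         breast  physical    29736 40.47428 48.05000  0.5659562
#> 2         breast      EQD2    29736 48.13294 63.67707  0.4844874
#> 3            fat  physical    23741 40.33962 47.87826  0.6422201
#> ...
```

The mixture means land on the generating tissue parameters (−110/−52 HU),
the composition percentages sum to 100 by construction, and the
fibroglandular rows show the higher mean dose because the boost was placed
there. `runPipeline(list(seed = 1, n_patients = 50, n_fractions = 15,
out_dir = "run1"))` executes all stages on a simulated cohort and writes
`features.csv`, `assignments.csv`, `segmentations.csv`, `dosimetry.csv`,
`models-summary.csv` and `models.json` into the run directory; a thin CLI
wrapper lives at `inst/scripts/breastcomp-cli.R`.

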