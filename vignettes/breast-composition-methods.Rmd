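---
title: "Breast composition on planning CT: models, defaults and design notes"
author: "breastCompRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breast composition on planning CT: models, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastCompRT)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the design choices made where more than one reasonable option
existed.

## Geometry and I/O

All voxel objects (`ImageVolume`, `StructureMask`, `DoseGrid`) live on
axis-aligned grids in patient-based mm. Arrays are stored in NIfTI order
(x, y, z); the world coordinate of voxel (i, j, k), 1-based, is
`origin + (c(i,j,k) - 1) * spacing`, i.e. voxel-*centre* coordinates.
Masks store voxel-centre membership. NIfTI is the interchange format for
volumes, masks and dose grids; contours travel as a plain CSV of polygon
vertices (`structure, contour_id, x_mm, y_mm, z_mm`) and are rasterized
with a voxel-centre-in-polygon (even-odd) rule per axial slice, so nested
contours make holes. Dose is resampled to the CT grid by trilinear
interpolation — exact on affine fields, never extrapolating: CT voxels
outside the dose extent get zero dose and an `outside` flag. Masks are
never interpolated.

The fraction count of a dose grid is deliberately *not* defaulted
anywhere: EQD2 conversion is meaningless without it, so `readDose()`,
`FractionationScheme()` and the pipeline config all require it explicitly.

## Skin cropping

Dose close to the skin is unreliable in treatment planning systems, and
the skin itself is not the tissue of interest, so breast contours are
cropped away from the body surface before any analysis (default margin
5 mm). The margin is *Euclidean*, computed as the exact anisotropic
distance from each voxel centre to the nearest voxel centre outside the
body mask (a separable Felzenszwalb distance transform in C++, respecting
anisotropic spacing); voxels at distance ≤ margin are removed. A geodesic
margin along the skin surface would be an alternative reading; Euclidean
was chosen as the standard morphological interpretation and is what the
distance-transform tests pin down. On a 1 mm grid the 5 mm default removes
exactly the five voxel layers nearest the surface; cropping is monotone in
the margin, and a margin that consumes the whole structure is an error
rather than a silent empty mask.

## First-order features and uniformity

Three features drive the global classification, computed over the cropped
breast: median and interquartile range of the raw HU values
(linear-interpolation quantiles, R type 7 — the convention must be fixed
because cohort clustering is sensitive to systematic quantile shifts), and
the histogram **uniformity**

$$U = \sum_i p_i^2, \qquad p_i = \frac{\text{count}_i}{n},$$

over a uniform-width histogram. U is 1 when all mass lies in one bin and
1/n for n equal bins; it is the same statistic whether applied to HU
(density characterisation) or to dose (homogeneity), and the package uses
one implementation for both. Bin width defaults: **25 HU** for intensity
(the de-facto first-order discretization; with fat SD near 5 HU it puts
the fatty archetype's uniformity in the observed 40 % regime) and
**0.25 Gy** for dose. Both are configuration knobs, and bin edges are
aligned to multiples of the width so that shifts by whole bins leave U
unchanged. U is reported as a fraction; multiply by 100 (or pass
`percent = TRUE`) for the percent form.

## Global density classification

K-means with k = 4 — four clusters *by design*, mirroring the four BI-RADS
density categories — on z-scored features. Standardization matters because
median HU (tens of HU), IQR (tens of HU) and uniformity (0–1) are on
incommensurate scales. The fit uses 10 restarts and a fixed default seed
(20140) so cohort runs are reproducible to the byte; the best-inertia
restart is kept.

Raw k-means indices are arbitrary, so clusters are *named* by ascending
centroid median HU: fat is the lowest-HU breast tissue, hence the
lowest-median cluster is `fatty` and the highest `extremely_dense`. Ties
(possible only in degenerate cohorts) break by descending centroid
uniformity, the fattier cluster being the more uniform one. For
ipsilateral/contralateral reproducibility two routes are exposed:
`projectClusters()` pushes new feature vectors through a fitted model
(nearest centroid in the model's z-space), while an independent refit plus
`compareClusterings()` reproduces a two-fit confusion analysis with
per-class agreement and overall accuracy.

## Per-patient tissue model

The composition model assumes the in-window breast HU histogram is a
two-component Gaussian mixture: a narrow fat peak and a broader
fibroglandular peak. The EM fit runs on a 1-HU weighted histogram (so it
is invariant to voxel order and fast at any breast size) with
deterministic initialization: component means at the weighted 25th/75th
percentiles, pooled SD, equal weights.

* **Fitting window**: initial default [−200, 100] HU excludes air, lung
  and high-HU outliers — surgical clips and calcifications fall outside
  and never enter the composition estimate. After the first fit the
  window is refined once to `[μ_fat − 2σ_fat, μ_fg + 2σ_fg]` and the
  mixture refitted, making the effective window per-case. The refinement
  trades a small truncation bias in the fibroglandular SD (about
  0.5–0.7 HU at calibrated separations) for robustness against water-like
  outliers such as seroma; means and weights are unaffected at the 1 HU /
  0.02 level, which is what composition estimates rest on.
* **Convergence**: relative log-likelihood gain < 1e-6, cap 500
  iterations (hitting the cap flags the fit rather than failing).
* **Collapse guard**: a component SD below 1 HU (or vanishing weight)
  aborts with a message suggesting a single-population input — a
  two-component fit to one population is not made to limp along.
* **Thresholds and priority**: tissue intervals are μ ± 2σ per component.
  The intervals commonly overlap; overlapping voxels are classified as
  **fat**, because the fat peak is the narrower and more distinct of the
  two, so membership of the tight fat interval is the stronger evidence.
  Voxels in neither interval stay **unclassified** — they are reported,
  never silently reassigned — and the three masks always partition the
  breast with percentages summing to 100 (of the complete breast volume,
  so the denominators are unambiguous).

The fat mixture *weight* is the natural fat-fraction estimate; across
fat fractions 0.2–0.9 at calibrated tissue separations its mean absolute
error stays well under 2 percentage points (asserted in the tests).

## Substructure dosimetry

Physical dose is converted voxelwise to the equivalent dose in 2-Gy
fractions with the linear-quadratic model,

$$\mathrm{EQD2}_i = D_i \, \frac{d_i + \alpha/\beta}{2 + \alpha/\beta},
\qquad d_i = D_i / n,$$

with α/β = 1.7 Gy by default (late breast effects). EQD2 equals the
physical dose exactly at 2 Gy/fraction and exceeds it above. Where a
sequential boost exists as a separate grid, each phase is converted with
its own fraction count and the results summed — the per-voxel fraction
size of a combined grid would belong to no actual fraction. Mean, max and
uniformity are then computed per structure (breast, fat, fibroglandular,
unclassified) for both dose forms. Because the substructures partition the
breast, the volume-weighted mean of substructure means equals the breast
mean to machine precision; the suite asserts this conservation on every
phantom. The per-bin (not per-voxel) reading of the uniformity statistic
is deliberate: per-voxel probabilities of a continuous dose would make
Σp² collapse to 1/n regardless of the distribution.

## Toxicity association

Grades are 0–3 per endpoint (pain, oedema, atrophy, induration) and
timepoint (immediately post-RT, 1 y, 2 y), from two sources. Clinician and
patient reports are merged by **maximum severity** with provenance
retained; both per-timepoint analysis and a maximum-over-time summary
column are available, since both readings of "severity per endpoint" are
defensible. Analysis is complete-case per endpoint-timepoint cell.

The model is proportional-odds ordinal logistic regression (via
`MASS::polr`), adopted as stated without a partial-odds fallback.
Candidate composition/dose variables are first screened for pairwise
collinearity at |r| ≥ 0.9; within a flagged pair the variable with the
better (lower-AIC) univariable fit for the current endpoint is kept — a
determinate rule where any choice is defensible. Selection is then greedy
forward AIC around a *fixed* baseline (demographic/treatment variables the
user declares; age, breast volume and boost by default — the config must
own this list because no single baseline is canonical), stopping when no
candidate lowers the AIC; backward selection from the full candidate set
is run alongside to flag disagreement. Complete cases are fixed over the
union of variables up front so every AIC in a run is comparable. The trace
records every comparison; accepted steps strictly decrease AIC by
construction, and the whole path is deterministic given the data.
Significance annotations use two tiers (p < 0.05, p < 0.001) with no
multiplicity correction — reported as a convention, not endorsed as
inference.

## The synthetic generator

`generateBreastPhantom()` builds a hemispherical breast on a body slab.
Tissue labels come from a Gaussian random field smoothed to a chosen
correlation length (FFT convolution; the field is random, so circular
wrap-around is immaterial) and thresholded at the fat-fraction quantile —
coarse correlation gives "heterogeneous" texture, fine correlation gives
"scattered". HU values are drawn per tissue; the four archetype
calibrations use the ipsilateral tissue means/SDs (fat −110(5) to −76(25),
fibroglandular −52(12) to 9(15) HU across fatty → extremely dense), with
invented-but-realistic defaults for fat fraction (0.85/0.68/0.50/0.32),
breast radius (62/55/48/42 mm, implementing the observed volume–density
coupling) and correlation length. Everything is deterministic given the
seed, and ground truth (tissue masks, outcome coefficients) is returned
machine-readably.

`generateCohort()` has two modes. `imaging = TRUE` builds a full phantom
and dose field per patient and *measures* the covariates with the
package's own dosimetry, so end-to-end truth genuinely flows through the
measured quantities; outcomes are then drawn from a proportional-odds
latent model (logistic noise, cutpoints 0.4/1.7/3.0 on the latent scale,
giving realistic grade prevalences near 40/15/5 % at null) on z-scored
covariates with user-specified coefficients, attenuated at later
timepoints (×1/0.75/0.55). Clinician and patient reports are two
independent mis-gradings (±1 level with probability 0.15, missing with
probability 0.05) of the same underlying grade. `imaging = FALSE` draws
per-patient HU samples and closed-form dose metrics from the same
archetype parameters — suitable for association studies at large n. The
tabular HU sampler includes a 35 % partial-volume fraction (a uniform
random mix of the two tissue intensities per voxel): real breast voxels
straddle tissue boundaries, and without this the two-Gaussian samples are
far more uniform than real breasts. The value was calibrated once so the
fatty archetype lands at the observed cluster profile (uniformity near
40 %, median near −105 HU, IQR in the tens of HU).

What the generator does **not** emulate: anatomy (no chest-wall curvature,
skin layer or axillary tail), seroma or surgically disturbed volumes,
scanner-specific noise/artefacts, and any dose-calculation physics (dose
fields are analytic: base + gradient + Gaussian boost). Passing tests
therefore demonstrate correctness of the algorithms under the stated
statistical model — not clinical performance on real CT, where contour
quality, seroma and acquisition differences add error sources the
phantoms deliberately lack.

## Study sizes and numerical choices

The test suite and the acceptance script use desk-scale study sizes chosen
as representative rather than exhaustive: mixture recovery at 1e5 voxels
over tens of seeds, 20–50 phantoms for segmentation/conservation checks,
10 × 200 patients for clustering recovery, 100 replicates at n = 2000 for
coefficient recovery, several hundred replicates for the type-I error
check, 50–100 stepwise runs at n = 1500, and 20 end-to-end cohorts of 400.
Degenerate inputs fail loudly everywhere: empty masks, single-level
outcomes, zero-variance features, collapsed mixture components,
margin-consumed structures and missing fraction counts are errors or
flagged skips, never silent defaults.

## Known limitations

* No DICOM surface: volumes, masks and dose travel as NIfTI (plus the
  contour CSV); fraction counts travel in configuration.
* The ±2 SD window refinement slightly shrinks the fitted fibroglandular
  SD under truncation (see above); thresholds inherit this, conservatively
  narrowing the fibroglandular interval.
* The proportional-odds assumption is adopted, not tested; stepwise AIC
  selection is used to demonstrate added value of composition variables,
  not to build a validated prediction model — penalised alternatives
  would be preferable for prediction.
* k-means cluster boundaries are cohort-relative: assignments are not
  transportable across cohorts without refitting or projection.
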