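---
title: "Whole-breast stiffness mapping from transmission ultrasound tomography: methods"
author: "ustiff package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-breast stiffness mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ustiff)
```

## The problem and the model

Ring-transducer ultrasound tomography (UST) of the pendant breast produces
co-registered coronal stacks of two transmission quantities: sound speed
(m/s), which is higher in fibroglandular ("dense") tissue and most solid
masses than in fat, and attenuation (relative units), which is near zero in
simple cysts and high in many cancers. Because a longitudinal pulse probes
the tissue's resistance to compression, the two quantities together act as a
surrogate for the bulk modulus: tissue reads as *hard* only where it is both
dense (fast) and attenuating, while a fast but transparent lesion (a cyst)
reads as *soft*.

`ustiff` implements this fusion and the analyses built on it:

1. **Per-breast normalisation.** Each stack is linearly rescaled inside the
   breast mask so its 1st percentile maps to 0 and its 99th to 1, then
   clipped. The scale is fitted per breast: the map is a *relative* stiffness
   optimised for contrast within that breast, not a calibrated modulus in
   pascals (no external standard exists for the fusion). Percentiles are
   estimated on a mask eroded by 2 in-plane voxels so that an artifactually
   stiff skin rim cannot dominate the scale; the rescaling itself is applied
   to the full mask.
2. **Fusion rule.** The default stiffness is the voxelwise geometric mean,
   `S = sqrt(ss_norm * att_norm)`. This is the simplest rule with the
   required boundary behaviour: `S = 0` wherever attenuation is 0 regardless
   of sound speed (cysts stay soft), `S = 1` only where both inputs are
   maximal, and `S` is monotone in each input. The proprietary production
   fusion is not public; a `weighted_mean` rule (including attenuation-only
   weights) is exposed for sensitivity analysis.
3. **Six-component segmentation.** K-means with k = 2 on within-mask sound
   speed separates fat from fibroglandular tissue; k = 3 on within-mask
   stiffness yields soft/intermediate/hard, echoing the BI-RADS elasticity
   descriptors. Intersecting the two partitions gives six components
   ({soft, intermediate, hard} x {fat, fibroglandular}) whose voxel-count
   volumes sum exactly to the breast volume. Clustering is fitted per breast
   (consistent with the per-breast stiffness scale) with k-means++
   initialisation, 10 restarts and ascending-centroid relabelling, so labels
   are stable and runs are deterministic given the seed. No morphological
   cleanup is applied: the known inclusion of boundary fat pixels near
   fibroglandular interfaces is reproduced, not fixed.
4. **High-pass spatial filtering.** Mass characterisation uses a filtered
   map that suppresses structures larger than 1.5 cm: per coronal slice,
   `F = S - G_sigma(S)` with the Gaussian FWHM equal to the 15 mm cutoff
   (sigma = 15/2.3548 mm, converted to pixels). The blur is mask-normalised,
   i.e. tissue near the breast outline is compared against tissue only —
   filtering across the water boundary would otherwise manufacture a bright
   rim that hijacks the renormalised scale. Filtering is 2-D per slice
   because review is slice-based and the 2.5 mm out-of-plane spacing is
   coarse relative to the cutoff. The filtered map is re-stretched to [0, 1]
   per breast so the 3-class clustering and the 0-1 stiffness indices stay
   on the same scale; a Fourier Butterworth kernel is available as an
   alternative (sharper cutoff, some ringing). Filtering is applied to mass
   characterisation only — whole-breast volumetrics always use the
   unfiltered map.
5. **Mass metrics.** Masses are described by single-slice polygon ROIs
   (traced on the most representative coronal image; metrics are computed
   strictly inside the contour). Pixels are selected by the even-odd
   centre-in-polygon rule. Per mass and per map (unfiltered/filtered):
   the stiffness index (mean 0-1 stiffness), the stiffness-class and
   six-component percentages, GLCM homogeneity
   (`sum P(i,j)/(1+|i-j|)` over a symmetric, normalised co-occurrence
   matrix; 8 uniform gray levels, the four standard offsets, averaged over
   offsets with at least one within-ROI pair — the common radiomics
   convention, config-exposed since the source analysis does not state its
   settings), and the size class from the equivalent circular diameter
   `d = 2 sqrt(area/pi)` with small defined as `d <= 1.5 cm` (the tie goes
   to small; the source text uses both "<=" and "<" — we follow the methods
   wording).
6. **Statistics.** Group contrasts use the Welch unequal-variance t-test
   (the published group spreads plainly differ, and the source says only
   "t-test"), Pearson chi-squared without continuity correction for
   frequency contrasts, and 5th-95th percentile intervals of per-mass
   indices (the published "5-95% C.I." ranges are far too wide to be
   confidence intervals of means, so they are read as percentile ranges of
   the per-mass distribution). Raw p-values are reported with a 0.05
   significance flag and no multiple-testing correction, matching the
   published reporting.

## The synthetic phantom

No public UST data set exists, so validation runs on a synthetic digital
breast phantom with ground-truth labels (`phantom_spec()`,
`generate_phantom()`).

* **Geometry.** Pendant breast on the clinical 0.75 x 0.75 x 2.5 mm coronal
  grid, nipple at slice 1, hemispherical radial profile reaching
  `breast_radius` at the chest wall. Outside the mask is water
  (1500 m/s, zero attenuation).
* **Tissue.** Fat at 1425 m/s and fibroglandular tissue at 1530 m/s; the
  fibroglandular field is a Gaussian-smoothed random field (8 mm correlation
  length by default) thresholded inside the mask at the quantile that
  realises the requested fibroglandular fraction, so the realised
  composition is quantisation-exact. Attenuation follows tissue class (fat
  0.20, fibroglandular 0.40 on the relative 0-1 scale) plus a smoothed
  within-class texture (RMS 0.18) so that dense tissue spans a range of
  stiffness, plus independent Gaussian acquisition noise per modality
  (5 m/s, 0.03). Absolute acoustic values are not published for this
  system; these defaults were chosen once for plausible contrast ordering
  (the analysis is explicitly relative) and are configurable.
* **Masses.** Spheres in mm selected by the centre-of-voxel test, with
  class profiles encoding the published qualitative signatures: cysts fast
  but transparent (1520 m/s, attenuation 0.02), fibroadenomas homogeneous
  and intermediate (1510 m/s, 0.45), cancers fast, attenuating and
  internally heterogeneous (1570 m/s, 0.85), fibrosis cancer-like
  (1555 m/s, 0.80). Internal heterogeneity is a smoothed random field at
  1.5 mm correlation — the lambda/2 in-plane resolution scale; a
  reconstruction cannot carry voxel-iid texture — with RMS amplitude 0.50
  (cancer), 0.40 (fibrosis), 0.10 (fibroadenoma), 0.05 (cyst) multiplying
  both acoustic contrasts. Overlapping masses are rejected so ground truth
  stays unambiguous.
* **Optional structures.** A 2-voxel high-attenuation skin rim (to exercise
  the skin-artifact exclusion); forced-fibroglandular spheres; and smooth
  Gaussian attenuation mounds (`att_mounds`) representing large hard
  parenchymal groupings with no boundary step.

`simulate_mass_cohort()` builds cohorts of phantoms carrying 10 mm masses of
each histology (five per phantom on a fixed ring of non-overlapping slots at
25 mm depth), runs the full pipeline, and measures each mass through a
circular ROI traced just inside its known outline on its central slice.

## The obscured-mass filtering experiment

`simulate_embedded_mass()` reproduces the scenario the high-pass filter is
designed for: a 10 mm cancer lying at the edge of a hard parenchymal
grouping (Gaussian mound, sigma 14 mm — FWHM about 33 mm, well above the
cutoff — peak attenuation elevation 0.9, centres 26 mm apart). On the
unfiltered map the grouping's core is stiffer than the mass and anchors the
top of the per-breast scale, so the hard cluster boundary cuts through the
mass and its hard share is diluted (the obscuration effect). Filtering
flattens the grouping while the mass keeps most of its local contrast
(a 10 mm disc retains about 74% of its central contrast under a 15 mm-FWHM
Gaussian subtraction, a 30 mm structure about 6%), so the hard boundary
relocates onto the mass and its hard share rises; a probe ROI over the
grouping core moves the other way.

Two design points found while constructing this experiment are worth
recording. First, the obscuring structure must be *adjacent* to the mass,
not exactly co-located with it: the filtered map measures each voxel against
its local neighbourhood, so suppressing a structure centred on the mass can
only lower the mass's own filtered values. Second, the grouping must be
smooth: a sharp-edged stiff disc leaves a bright edge ring after filtering
(the step survives any linear high-pass) which takes over the hard cluster.
Real parenchymal groupings blend into their surroundings at reconstruction
resolution, which the Gaussian mound models.

## What the phantom does and does not show

The phantom reproduces: the fat/fibroglandular composition (recovered to
within quantisation error), the partition arithmetic of the six components,
the qualitative mass signatures and their ordering (stiffness index cancer >
fibroadenoma > cyst; homogeneity cancer < fibroadenoma), the direction of
the small-mass filtering effect, and exact null calibration of the group
comparison. Passing these tests supports the pipeline's correctness, not
clinical performance on real breasts.

Known limits:

* Under 3-class clustering the phantom's dense tissue lands almost entirely
  in the intermediate and hard classes, whereas the published cohort found
  most fibroglandular tissue soft (soft/intermediate/hard roughly 29/40/31
  within dense tissue). A single attenuation baseline plus smooth texture
  is too narrow a model for the within-class stiffness distribution of real
  dense tissue; the package therefore validates the fibroglandular/fat
  split against the published composition but not the internal softness
  split.
* With the geometric-mean rule, stiffness on a phantom with shared tissue
  structure correlates strongly with sound speed (r around 0.9), because
  `sqrt(ss_norm * att_norm)` is monotone in sound speed and both inputs are
  elevated in the same tissue. The published near-zero correlation
  (0.0048) therefore cannot arise from this rule on structured data; it
  evidently reflects the proprietary fusion. The package demonstrates the
  independence property in the configuration where it is mathematically
  attainable — attenuation-weighted fusion on independent noise fields —
  and exposes the fusion weights rather than guessing the production ones.
* Mass metrics are single-slice, as in the source analysis; no volumetric
  ROIs. There is no acoustic wave propagation, no reflection imaging, no
  automatic breast masking (the phantom supplies the mask; external data
  must bring one).

## Numerical choices

* Percentiles: type-7 (linear interpolation between order statistics)
  everywhere.
* Gaussian smoothing uses truncated kernels (4 sigma) with edge
  renormalisation, so smoothing preserves constants exactly and the
  high-pass of a constant slice is exactly zero.
* K-means: k-means++ initialisation, 10 restarts, Lloyd iterations, best
  within-SSE kept; verified against an exhaustive 2-partition search and a
  dynamic-programming optimal 1-D k-partition oracle. Degenerate inputs
  (fewer distinct values than k) are rejected; the sound-speed caller falls
  back to all-fat with a warning.
* Constant stacks normalise to all zeros with a warning; zero-variance
  correlations return `NA` with a warning; GLCM on an ROI with no valid
  pixel pair returns `NA` with a warning.
* Problem sizes in the test-suite and acceptance runs (96^2 x 16 voxel
  phantoms for cohort work, 200^2 x 40 for composition recovery, 20 masses
  per class, 200 null replicates) were chosen as the smallest sizes at
  which the checked quantities are stable; all are parameters, not limits.

## Reproducing the published-table arithmetic

The published cohort summaries bundled as `reference_cohort_volumes()`,
`reference_small_cancer_filtering()` and `reference_mass_counts()` allow the
package to recompute the tables' internal arithmetic (component percentages,
tissue splits, the 23.1-point hard-component increase for small filtered
cancers, masses per woman, the fibrotic share of small solid masses).
`scripts/acceptance.R` recomputes these together with the simulation-based
quantities; see the README for how to run it.

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(seed = 1))
fit <- breast_stiffness(ph$ss, ph$att, ph$breast_mask, seed = 1)
summary(fit)
```
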