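---
title: "Anatomical standardization and Z-scoring of torso FDG-PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical standardization and Z-scoring of torso FDG-PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petnorm)
```

## The problem

The standardized uptake value (SUV) of FDG-PET is only semi-quantitative:
a raw SUV of 2 can be alarming in one tissue and unremarkable in another,
and physiologic accumulations (bladder, brain, myocardium) dwarf many true
lesions. The remedy used routinely in brain PET (SPM, 3D-SSP) is
statistical: deform every scan onto a common anatomy, accumulate the
voxel-wise normal range from healthy scans, and express a patient's uptake
as a Z-score

$$Z(x,y,z) = \frac{P(x,y,z) - M(x,y,z)}{SD(x,y,z)},$$

where $P$ is the deformed patient SUV and $M$, $SD$ the voxel-wise mean and
standard deviation of the deformed normal cohort. `petnorm` implements this
scheme for the torso, where no commonly accepted standardization exists:
the deformation must cope with physique variation (height, width, girth),
organ position variation (liver, bladder), and body-surface differences.

## The registration procedure

Every scan passes through three rule-based stages, all automatic:

1. **Physique registration.** The body is extracted by thresholding SUV at
   0.5 and keeping the largest 26-connected component. Six planes bound
   the torso: the neck--shoulder plane NS (axial slice of minimum body
   area, searched in the superior portion of the body), the two
   arms--chest planes AC (the axilla dips in the sagittal profile of body
   area), the thigh--hips plane TH (scanning tail-to-head, the first axial
   slice where the two large thigh components have united), and the
   anterior/posterior planes A/P (first and last coronal planes with body
   below NS, so a protruding head cannot bias them).
2. **Organ registration.** The bladder, made conspicuous by urinary
   tracer, is segmented per coronal plane by adaptive thresholding; the
   mean z of its 2D label centroids is the BL plane. The liver is
   segmented the same way in the patient-right/superior quadrant; its apex
   (the liver--lung boundary) is the LV plane. The four axial levels
   (NS, LV, BL, TH) crossed with the AC and A/P planes yield 16 corner
   landmarks.
3. **Surface registration.** Control points are placed where rays cast
   from each slice centroid (every 15 degrees, on every 5th axial slice
   across the TH--NS span) last leave the body, on both the standard and
   the cuboid-registered subject; a 3D thin-plate spline (TPS)
   interpolates the residual surface mismatch.

Patient scans and normal scans travel through exactly the same pipeline;
the normal model is then the per-voxel mean and sample SD over the
standardized normals, stratified by sex.

## Design choices in the open parts of the procedure

Several steps admit more than one faithful reading; the package picks one
and exposes the alternative where reasonable:

* **Piecewise affine cuboid mapping.** A single affine transform cannot
  satisfy 16 landmark constraints. The 16 corners are compatible with an
  axis-aligned map that is linear in x (through the AC planes), linear in
  y (through A/P) and piecewise linear in z through the TH, BL, LV and NS
  knots -- three slabs that agree exactly on the shared organ planes and
  map every corner exactly. This is the default (`slab_mode =
  "piecewise"`). A global 12-dof least-squares affine over the 16 pairs is
  available (`slab_mode = "global"`) for comparison.
* **Pull-back resampling.** Rather than forward-warping voxels and filling
  gaps, the transforms are fitted in the direction standard space to
  subject space, and the output grid is scanned with nearest-neighbor
  pull-back. No gaps can arise, and nearest-neighbor guarantees that no
  SUV value is invented by interpolation.
* **TPS kernel.** In 3D the biharmonic kernel is $U(r) = -r$ (the
  conditionally positive definite sign convention); the familiar
  $r^2\log r$ is the 2D kernel. With smoothing $\lambda = 0$ (the
  default) the spline interpolates its anchors exactly; $\lambda > 0$
  trades anchor fidelity for smoothness and is well-posed for all
  $\lambda$ with this kernel sign. Coincident anchors -- adjacent rays
  hitting the same voxel on a narrow slice such as the neck -- are merged
  with their targets averaged.
* **Surface point counts.** The number of control points follows from the
  standard body's TH--NS span and the 15-degree/5-slice spacing, so it is
  a property of the chosen standard body, not a constant of the method.
* **Sample SD.** The model uses the $n-1$ denominator: it estimates the
  population spread of normals from a sample. Accumulation is a streaming
  Welford pass in input order, bit-reproducible across runs and
  permutation-invariant to within floating-point reduction order (the
  test suite checks agreement with a two-pass recomputation to 1e-6
  relative).
* **SD floor.** Voxels with model SD below 0.05 SUV (air, mask edges) are
  flagged invalid rather than allowed to produce explosive Z values; the
  floor is configurable (`sd_floor`).
* **Indices.** All voxel indices are 1-based (R convention); axis 1 runs
  patient left-to-right, axis 2 anterior-to-posterior, axis 3
  inferior-to-superior. Fractional plane positions round half-up.
* **Detector tunables.** The NS search band (superior 35% of the body z
  extent, ignoring slices under 5% of the maximum axial area), the
  "large component" size for TH (50 voxels), the AC profile smoothing
  (3-slice moving average, dips below 60% of the central peak), the
  bladder threshold (max of 5.0 SUV and 3 x soft-tissue median, searched
  in the inferior 40% of the cuboid and medial 50% of the AC span), the
  liver threshold (1.3 x soft-tissue median, patient-right and superior
  half, tested against each candidate region's centroid), and the BL
  fallback (30% of the TH--NS span when no bladder is found, flagged in
  the report) are all surfaced in `pet_config()`. None of these have
  canonical published values; the defaults are chosen for robustness on
  noisy PET body masks and are validated by the phantom suite.

## The phantom: what it emulates and what it does not

Clinical normal databases cannot be redistributed, so the package ships a
procedural torso phantom (`generate_phantom()`) providing complete ground
truth: stacked elliptical cross-sections form thighs, hips, waist, chest
with arms separated by an air gap of at least two voxels, shoulders, a
neck with a designed unique area minimum, and a head; ellipsoidal brain,
lungs, liver and bladder are painted with configurable mean SUVs (defaults:
soft tissue 1.0, lung 0.6, liver 2.0, brain 7.0, bladder 12.0 -- chosen so
each rule-based detector is well-posed, with the lung kept above the body
threshold so the body support is exact). Additive Gaussian noise (SUV is
a reconstructed quantity, for which Gaussian is the conventional
approximation; default SD 0.1) and spherical lesions of known SUV can be
added. `phantom_population()` emulates a normal database: physique scales
and organ SUVs jitter by +/-10% (uniform), and the bladder by +/-33% --
urinary filling varies far more between subjects than parenchymal uptake,
which is exactly why a very high bladder SUV maps to a low Z-score.

The phantom does **not** emulate PET physics (scatter, attenuation,
partial volume, reconstruction texture), brown fat, myocardial uptake
variability, arm-pose differences, or pathology other than planted
spheres. Passing the phantom suite therefore demonstrates that the
rule-based detectors, the landmark algebra, the registration operators and
the statistics are implemented correctly and are robust to physique
variation and moderate voxel noise -- not that the pipeline is clinically
validated on real scans.

## Problem sizes used by the validation suite

The test and acceptance suites work on 64^3 grids: a 50-phantom normal
cohort plus 20 lesioned patient phantoms for the end-to-end discrimination
property (planted lesions at local mean + 4 SD must reach Z >= 3 while
bladder voxels of far higher raw SUV stay below Z = 2), 200 noiseless and
200 noisy phantoms for plane-detector recovery, and 25 standardized
phantoms for the streaming-statistics oracle. These sizes make the whole
suite run in minutes while leaving every property statistically
meaningful.

## Known limitations

* The rule-based detectors presume torso coverage from thighs to head
  with arms down and separated; armless or cropped scans fail with
  explicit diagnostics rather than degrading silently.
* An empty (tracer-free) bladder triggers the BL fallback plane; the
  registration then relies on physique planes alone between TH and LV.
* Nearest-neighbor resampling preserves SUV values exactly but quantizes
  geometry to the voxel grid; landmark positions after standardization
  are reproducible only to about one voxel.
* The normal model is purely voxel-wise: no spatial regularization, no
  covariates (age, BMI, glucose), and sex strata are mandatory and never
  mixed.
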