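---
title: "Measuring total kidney volume with tkvseg: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring total kidney volume with tkvseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkvseg)
```

# The problem

In autosomal dominant polycystic kidney disease (ADPKD), both kidneys
enlarge progressively as cysts grow, and total kidney volume (TKV) — the
sum of left and right kidney volumes — is the accepted imaging surrogate
for disease severity and progression. The reference way to obtain TKV
from T2-weighted MRI is manual planimetry: a radiologist traces both
kidneys on every slice, and traced areas are integrated across slices.
`tkvseg` implements a semi-automated replacement: a 2D U-Net segments
the kidneys slice by slice, classical morphology repairs the predicted
masks, and the DICOM geometry converts pixel counts into millilitres.

The pipeline has five stages, each usable on its own:

1. **Geometry I/O** — read a DICOM series, extract PixelSpacing,
   SliceThickness, SpacingBetweenSlices, Rows, Columns and orientation;
   resample slices to the model grid (`readDicomSeries()`,
   `prepareForModel()`).
2. **Dataset** — rasterise polygon annotations (Labelme-style JSON) into
   binary masks, split train/validation, and randomly augment each
   training pair every epoch (`polygonsToMask()`, `splitTrainVal()`,
   `augmentPair()`).
3. **Segmentation** — train the modified U-Net with a Dice loss
   (`buildUnet()`, `trainUnet()`, `predictStack()`).
4. **Post-processing** — binarise at the fixed cut, fill holes, remove
   speckle, split left/right (`postprocessStack()`).
5. **Volumetry and evaluation** — planimetric and mid-slice volumes,
   Dice/Jaccard, agreement tables and Bland–Altman analysis
   (`totalKidneyVolume()`, `midsliceTkv()`, `agreementTable()`,
   `blandAltman()`).

A synthetic phantom generator (`generatePhantom()`, `cmdSimulate()`)
provides cases with exactly known masks and volumes so that the whole
chain can be exercised and tested without patient data.

# The segmentation model

The network is the classic encoder–decoder U-Net with minor
modifications:

* padding-same 3×3 convolutions everywhere, so feature maps keep their
  spatial size and the output mask matches the input grid;
* He-initialised weights, ReLU activations, and a sigmoid head giving
  per-pixel kidney probabilities in (0, 1);
* one dropout layer (rate 0.2) at the end of the contracting path;
* 2× nearest-neighbour upsampling followed by a 3×3 convolution in the
  decoder, with the symmetric encoder feature map concatenated at each
  resolution;
* a single foreground class: left and right kidney polygons are merged
  into one training target, and laterality is recovered geometrically in
  post-processing. This keeps the head a single sigmoid; nothing in the
  data suggests the two kidneys differ in appearance in a way a
  two-class head would exploit.

Training minimises the smoothed Dice loss

$$L = 1 - \frac{2\sum_i p_i t_i + \varepsilon}{\sum_i p_i + \sum_i t_i + \varepsilon},$$

with $\varepsilon = 10^{-6}$, which directly targets the overlap metric
used for evaluation (DSC $= 2TP/(2TP+FP+FN)$) and is robust to the
foreground/background imbalance of kidney slices. The optimiser is Adam
(β₁ = 0.9, β₂ = 0.999) under a warm-up exponential-decay schedule: the
learning rate ramps linearly from 0 to `peakLr` over `warmupEpochs`,
then decays by `decayRate` per epoch. Early stopping monitors the mean
slice-wise validation DSC at the 0.5 threshold and restores the best
epoch's weights.

The implementation is pure R: convolutions are expressed as im2col
gathers followed by BLAS matrix products, with analytically derived
backward passes (verified against numerical differentiation in the test
suite). This keeps the package dependency-free and fully inspectable;
the price is that it is only practical at the small problem sizes used
here, not at GPU scale.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `depth` | 4 | down-sampling stages; phantom experiments use 2 |
| `baseFilters` | 32 | first-stage filters, doubled per stage; phantoms use 8 |
| `inputSize` | 256 px | model grid; must be divisible by `2^depth` |
| `dropoutRate` | 0.2 | bottleneck dropout |
| `batchSize` | 10 | minibatch size |
| `maxEpochs` | 500 | epoch cap; early stopping usually fires first |
| `peakLr` | 1e-3 | post-warm-up learning rate |
| `warmupEpochs` | 5 | linear ramp length |
| `decayRate` | 0.9/epoch | exponential decay; 0.97 for short phantom runs |
| `patience` | 20 epochs | early-stopping patience on validation DSC |
| `rotationMaxDeg` | 5° | augmentation rotation range |
| `shiftMaxFrac` | 0.10 | augmentation shift range (fraction of dim) |
| `zoomMaxFrac` | 0.10 | augmentation zoom range |
| flips | off | disabled: laterality is anatomically meaningful |
| `minSizePx` | 25 px | despeckle cut on the native grid |

The default decay of 0.9 per epoch is calibrated for runs of hundreds
of epochs; in the 40–60-epoch phantom experiments it would shrink the
learning rate a hundred-fold before convergence, so those runs use
0.97. The despeckle cut is expressed in pixels on the native grid;
since a pixel's physical area varies with PixelSpacing, users working
at unusual resolutions should rescale it (25 px at a typical 1.5 mm
in-plane spacing is ~56 mm², far below any kidney cross-section).

# Conventions and numerical choices

* **Pixel coordinates** are row-major, origin top-left, 0-based, with
  pixel (i, j) centred at coordinate (i, j); resampling uses the
  pixel-center convention `src = (dst + 0.5) · n_in/n_out − 0.5`.
* **Rasterisation rule**: a pixel belongs to a polygon iff its center
  is inside (even-odd rule) or on the boundary. This makes an
  axis-aligned rectangle with corners on pixel centers cover exactly
  (w+1)(h+1) pixels and converges to the shoelace area for large
  polygons.
* **Binarisation**: one cut for the whole pipeline — probability ≥ 0.5,
  equivalently grayscale ≥ 128 on 0–255 integers (127 → 0, 128 → 1).
* **Connectivity pair**: hole detection uses 4-connected background,
  component analysis 8-connected foreground — the standard
  complementary pair that avoids topological paradoxes.
* **Stage order** is fixed: binarise → fill holes → despeckle →
  split. Filling before despeckling matters: a thin ring (e.g. a
  cyst-dominated cross-section) survives because its filled area, not
  its 1-px perimeter, meets the size cut.
* **Laterality**: per-slice 8-connected components are assigned by
  centroid column relative to the image midline, radiological
  convention (image-left = patient-right); a centroid exactly on the
  midline goes to patient-left, and side flips between adjacent slices
  raise a warning.
* **Volumetry**: volume = Σ slice area × Δ, with Δ = SliceThickness by
  default. SpacingBetweenSlices is also extracted and can be selected
  (`spacingMode = "between_slices"`); when the two differ by more than
  5% a message is emitted, since gapped or overlapping acquisitions
  make the choice material.
* **Mid-slice comparator**: the uncorrected prism form — middle
  kidney-bearing slice area × number of kidney-bearing slices × Δ,
  lower-median index on even counts. For ellipsoids this overestimates
  volume by a factor approaching 3/2, which the tests assert on
  phantoms; no ellipsoid correction factor is applied, and the method
  is provided as a comparator, not a recommended estimator.
* **Slice ordering**: by ImagePositionPatient projected on the slice
  normal, falling back to InstanceNumber; RescaleSlope/Intercept are
  applied when present so intensities are on the stored-value scale the
  annotators saw; absent optional tags are reported, never silently
  defaulted.
* **Degenerate inputs**: empty slices contribute zero area; an empty
  kidney yields 0 mL rather than an error (apex/base slices are
  legitimately empty); Dice/Jaccard of two empty masks is defined as 1.

# Agreement statistics

`agreementTable()` reproduces the usual per-case layout: absolute
difference |pred − truth| in mL and percent difference with the ground
truth as denominator, summarised by mean and *sample* SD (n − 1). Both
choices are deliberate and tested: they reproduce the reference tables
bundled under `inst/extdata/` to the printed precision.

Bland–Altman percent differences are a known source of ambiguity: the
denominator may be the pairwise mean (the textbook choice), the
reference, or the prediction, and the sign convention varies.
`blandAltman()` defaults to signed (pred − truth)/pairwise-mean × 100
but computes and reports the bias and limits of agreement under all
three denominators, so a reader can match any published convention
rather than guess. The limits are bias ± 1.96 SD exactly.

`compareGroups()` applies a two-sided two-sample test, Student's t when
both samples pass a Shapiro–Wilk normality check and Mann–Whitney
otherwise, mirroring common practice in clinical reports.

# The phantom generator

`phantomSpec()` describes a synthetic abdominal series: two
non-overlapping ellipsoidal kidneys (semiaxes and centers in mm, left
kidney at +x), optional bright spherical cysts clipped to the kidney
interior, background/parenchyma/cyst intensity levels on the 0–255
scale, and additive Gaussian noise. Truth masks are the exact noiseless
ellipsoid cross-sections — cysts count as kidney, as they do clinically
in TKV — and both voxel-counted and analytic (4/3 π abc) volumes are
carried with each case. Orientation relabels the stacking axis: coronal
stacks section the long axis in-plane, mimicking the elongated kidney
outlines of coronal MRI.

The default study conditions are a 64×64 grid at 4 mm in-plane, 20
slices of 6 mm, kidney semiaxes (30, 22, 52)/(28, 20, 48) mm at ±44 mm,
noise SD 8, three cysts of 4–10 mm per kidney; cohorts jitter semiaxes
by ±15% and lateral centers by ±5 mm per case. These were chosen once
as a realistic small-FOV caricature of abdominal T2 imaging whose
training runs complete in minutes on a single CPU; the test experiments
train a depth-2, 8-filter network on three such cases (two training,
one held out — about 36 training slices of which each epoch sees a
fresh augmented version).

What the phantom does **not** emulate: MR physics (coil shading, bias
fields, partial-volume blur), other abdominal organs and their contrast,
irregular cyst-deformed kidney contours, inter-annotator variability,
and realistic patient-to-patient anatomy. Passing the phantom
experiments therefore demonstrates that the machinery — data plumbing,
optimisation, inpainting, geometry-correct volumetry — works end to
end; it does not certify clinical-grade accuracy on real MRI, which
would require the original patient data.

# Reference agreement tables

Two 10-case TKV agreement tables (ground truth vs automated
measurement, one axial and one coronal cohort) are bundled as
`inst/extdata/agreement_{axial,coronal}.csv`. They drive the arithmetic
tests (means, sample SDs, percent differences) and the worked example
in the README; the package recomputes every derived column from the two
raw volume columns.

# Known limitations

* The pure-R network is CPU-bound; the 256×256, depth-4 default
  configuration is provided and correct but training it for hundreds of
  epochs is only realistic on small datasets or with patience.
* The DICOM codec covers uncompressed Explicit VR Little Endian
  single-frame grayscale series — the format it writes and the common
  export format of MR archives. Compressed transfer syntaxes,
  multi-frame objects and sequences are out of scope.
* Laterality by midline centroid assumes a roughly centred patient;
  grossly off-centre acquisitions would need the (logged) cross-slice
  consistency warnings to be heeded.
* The mid-slice comparator is the uncorrected prism variant; published
  mid-slice methods sometimes include an ellipsoid correction factor,
  so absolute mid-slice values are comparable only in ratio terms.

# Session info

```{r}
sessionInfo()
```
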