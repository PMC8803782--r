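---
title: "Detecting pathological mediastinal lymph nodes in FDG-PET/CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pathological mediastinal lymph nodes in FDG-PET/CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Staging of non-small-cell lung cancer depends on whether mediastinal lymph
nodes are metastatic. On a whole-body [18F]FDG-PET/CT, pathological nodes
show up as focal tracer uptake (high SUV) in the mediastinum; reading every
slice is slow and inter-reader agreement is limited. `mediastinet`
implements a fully automated cascade that goes from the raw co-registered
CT (Hounsfield units) and PET (SUV) volumes to a list of predicted node
locations, with node-level statistics that can be compared against a
human reader.

The cascade has two phases because the raw task is extremely unbalanced (a
few cubic centimetres of node in a whole-body volume):

1. **Candidate generation** — a 2D U-Net proposes high-sensitivity
   candidate regions slice by slice.
2. **False-positive reduction** — a 3D residual network classifies
   overlapping 64-mm cubes over those regions, and the per-cube
   probabilities are aggregated into a per-voxel summed score.

## Preprocessing

Both modalities are resampled to a 1-mm isotropic grid, the thorax is
located from the CT by a crude lung segmentation, and intensities are
clipped and standardised:

* **Resampling.** Separable cubic-spline interpolation (local Catmull-Rom
  kernel). A local cubic convolution was chosen over a global B-spline fit
  because it is interpolating at the nodes (constants and linear ramps are
  reproduced exactly, which the test suite exercises), needs no linear
  solve, and behaves identically at every grid size. Output lengths are
  `round(n * spacing / target)` per axis, preserving the physical slab to
  within one voxel; beyond the first/last voxel centre the edge value is
  extended.
* **Lung finding.** Voxels at or below -400 HU count as air (the printed
  rule leaves the boundary value unassigned; the air side is harmless and
  was fixed once). A 2-iteration binary closing then a 7-iteration binary
  opening (face-connected element, in 3D — the printed description does
  not say 2D-per-slice or 3D; 3D is the natural reading for volumetric
  masks and removes inter-slice speckle too) clean the mask. Components
  with any voxel within 25 voxels of the x/y border are exterior air and
  are dropped; the z axis is exempt because a whole-body scan necessarily
  reaches the first and last slice with patient tissue. The largest
  remaining 26-connected component is taken as the lungs; size ties break
  to scan order, deterministically. No special trachea handling is done.
* **Cropping.** Only slices within the lung z-range are kept; each slice
  is symmetrically centre-cropped to 256 x 256. Slices smaller than the
  window are padded with air-equivalent values (-1000 HU / 0 SUV); the
  clinical field of view always exceeds 256 mm, so padding only arises for
  synthetic phantoms.
* **Intensities.** CT clipped to [-1000, 1000] HU, PET to [0, 8] SUV, then
  one dataset-level standardisation (zero mean, unit variance per modality,
  pooled over all voxels of the training crops). The statistics are
  persisted and reused at inference, never refitted: a dataset-level affine
  map keeps absolute differences between patients meaningful.

Everything above is deterministic and needs no manual input.

## Phase one: U-Net candidate generation

Point annotations, not contours, mark the nodes, so training labels are
15-mm spheres centred on the node positions (nodes are at most ~30 mm in
diameter, so the sphere covers them). The U-Net sees full 256 x 256
two-channel (CT, PET) slices so it can learn mediastinal context; only
slices containing at least one positive label voxel are used for training.
Training uses a soft Dice loss and Adam at learning rate 1e-5 for 20
epochs (defaults; the scaled-down profile described below shrinks this).

At inference every slice is run through the network, probabilities are
binarised at 0.5 (the sigmoid midpoint; the choice is configurable),
stacked into 3D, and 26-connected components become candidate regions.
Regions under 300 voxels are discarded and the survivors dilated by 3
face-connected iterations; dilated regions that touch are merged, since
phase two operates on contiguous regions. Dilation after filtering is the
printed order. Candidate sensitivity is measured after dilation, on node
centre points.

## Phase two: cube classification and aggregation

Candidate regions are covered by 64-mm cubes on a regular 8-mm lattice.
The lattice is anchored at the crop origin (per volume, not per region),
so cube placement is deterministic and independent of how regions happen
to be segmented; a lattice point is used iff its voxel lies inside a
candidate region. A cube is labelled positive iff a node lies within 16 mm
of its centre (inclusive at the boundary). Negatives are randomly
undersampled by a factor of eight, once, before training.

The classifier is a 3D residual network — by default a 50-layer bottleneck
architecture (3-4-6-3 blocks) — trained with cross-entropy, batch size 32,
Adam at 1e-5, with on-the-fly augmentation by random axis flips and
right-angle rotations in x, y and z. Right-angle rotations (rather than
arbitrary angles) keep augmentation interpolation-free on the isotropic
cubes. Depth and width are configuration values, so CPU-scale runs shrink
the network without touching any pipeline semantics.

At inference each enumerated cube receives a pathological probability (no
augmentation), and every voxel's **summed score** is the sum of the
probabilities of all cubes whose extent contains it. The published
aggregation sums "predictions"; this package sums probabilities rather
than binarised votes — the threshold of 18 against a maximum coverage of
512 cubes is consistent with either reading, and probabilities retain
calibration information. Voxels with summed score strictly above the
threshold (default 18) form the predicted node regions (26-connected
components). The threshold can be re-tuned on a validation cohort by
minimising FP + FN over an integer sweep, ties resolved toward the larger
threshold (fewer false positives).

## Transfer to a second scanner

Scans from a newer scanner differ in voxel size, contrast and noise
(domain shift). The transfer procedure keeps phase one frozen: candidate
cubes come from the unchanged U-Net, and only the phase-two classifier is
trained further, with the identical loop at a much smaller learning rate
(1e-8 at full scale, against 1e-5 for initial training; the scaled-down
profile keeps the same two-orders-of-magnitude reduction relative to its
own training rate).

## Evaluation conventions

A predicted region containing at least one node centre is a true positive
(counted per node, so TP + FN equals the node total); a region containing
none is a false positive (counted per region); an uncovered node is a
false negative. Sensitivity is TP/(TP+FN) and FPs/patient is FP/patients.
Because one giant region would trivially cover everything, region extents
are also reported so predictions can be checked to actually localise.

Cohen's kappa against the reference reader needs true negatives, which
node-level detection does not define; the package follows the fixed
convention TN = 8.3 x patients - (TP + FP + FN), with 8.3 nodes per
patient taken from the comparison literature. The TN may be fractional
and is used as-is. Confidence intervals are exact Clopper-Pearson
(binomial-tail inversion, computed via beta quantiles): for sensitivity on
(TP, TP+FN); for FPs/patient on (FP, round(8.3 x patients)) rescaled to a
per-patient rate — a convention-dependent choice that is labelled as such
in every report. Kappa magnitudes are qualified with the Landis-Koch
bands. Specificity is deliberately not reported: without a defined
per-patient node denominator it is not comparable across studies.

## The phantom generator

Real scans are private, so the package ships a parametric thoracic phantom
that exercises every pipeline stage with known ground truth:

* a soft-tissue body (0 HU) on an air background, with two air-filled lung
  ellipsoids (-800 HU) joined by a 12-mm-radius bronchial air bar so that
  the largest interior air component is both lungs, as in patients;
* a mediastinal compartment between the lungs in which spherical nodes
  (8-30 mm, soft-tissue HU) are planted with a minimum separation;
* a PET with per-patient soft-tissue background (1-2 SUV), low lung
  uptake, node uptake 3-8 SUV above background, at least one distractor
  hot spot outside the mediastinum (the thyroid-nodule / inflammation
  false-positive analogue), and additive Gaussian noise;
* two scanner profiles: 4-mm PET voxels with noise SD 0.20 and unit
  contrast gain ("scanner 1"), and 2.5/2.8-mm PET voxels with noise SD
  0.15 and contrast gain 1.4 ("scanner 2" — the newer scanner's higher
  contrast enters as a single multiplicative gain, since the pipeline only
  consumes SUV maps). No reconstruction, attenuation or motion physics is
  simulated.

Per-patient node counts are drawn from the pooled cohort split (52% of
patients have no nodes; the 4+ band continues as 4 + Poisson(1.3), giving
that band a mean near 5.3 nodes). The CT native grid is 192 x 192 x 160
at 2 mm, resampled to 1 mm by the pipeline. All randomness derives from
one seed; per-patient seeds are drawn deterministically from the cohort
seed.

What passing phantom tests shows — and what it does not: the phantoms
validate the *plumbing and learnability* of every stage (geometry,
coordinate conventions, label construction, training dynamics, score
aggregation, evaluation), but their contrast is idealised; ellipsoid
anatomy, Gaussian noise and clean backgrounds make the detection task far
easier than clinical data, so phantom sensitivities say nothing
quantitative about performance on patients.

## Scaled-down profile and problem sizes

`scaled_down()` shrinks only capacity and schedule: U-Net base width 2
with 2 levels, 3 epochs, learning rate 1e-3, at most 160 training slices;
ResNet with basic blocks (1, 1), widths (4, 8), stem width 2, 3 epochs,
batch 8, learning rate 3e-3, fine-tuning at 3e-5 (the same
two-orders-of-magnitude reduction relative to its training rate that the
full-scale configuration uses). Geometry (1-mm grid, 256-crop, 64-mm
cubes, 8-mm lattice, 16-mm labels, threshold rules) is identical to the
full configuration. The packaged end-to-end experiment uses 12 training
and 6 test phantoms on scanner 1, and 6 + 6 phantoms on scanner 2 for the
transfer arm; with the higher learning rate the shrunken networks converge
on the easy phantom task within 3 epochs. The classifier head is
zero-initialised so training starts from probability 0.5 — the plain
residual trunk (no batch normalisation) otherwise produces large initial
logits whose confident errors destabilise the first epochs.

## Numerical choices and degenerate inputs

* Rounding for comparisons against printed tables is half-up at 2
  decimals (printed clinical tables round half up; R's default rounds half
  to even).
* Recovery of integer counts from printed rates scans all candidate
  numerators and *errors* on zero or multiple matches rather than
  guessing.
* Morphology treats outside-the-grid as background; erosion therefore
  peels the volume faces, matching the standard scipy convention and the
  brute-force oracle in the test suite.
* Component labelling is BFS in scan order, so labels (and all tie-breaks
  that depend on them) are deterministic.
* Zero-variance training data, empty lung masks, nodes outside a grid,
  unlabelled training sets and single-class cube sets all raise typed
  errors early rather than propagating NaNs; sensitivity with zero nodes
  returns NaN with a warning.
* The CNN engine runs in double precision, single-threaded, with all
  randomness drawn from R's RNG; identical seeds and data reproduce
  identical loss traces and parameter hashes. He initialisation is used
  throughout; residual blocks are plain (no batch normalisation), which at
  these depths trains stably and keeps the engine exactly reproducible.

## Known limitations

* The phantom's contrast model is a single gain knob; domain shift between
  the two profiles is milder than between real scanners.
* The U-Net and ResNet are faithful in structure but the exact published
  layer widths of the original architectures were not available; both are
  configurable, and the defaults record the published depth (50 layers,
  bottleneck 3-4-6-3).
* Kappa confidence intervals are not computed (no published method to
  follow); the point estimate is reported.
* DICOM support covers uncompressed explicit-VR little-endian series, the
  common scanner export; compressed transfer syntaxes are out of scope.
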