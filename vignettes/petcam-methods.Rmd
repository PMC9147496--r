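---
title: "Weakly supervised PET tumour segmentation with prior-constrained class activation maps"
author: "petcam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised PET tumour segmentation with prior-constrained class activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcam)
```

## The problem

Radiomic outcome prediction needs a 3D tumour segmentation, but voxel-level
annotation of PET volumes is expensive, subjective and rarely available at
scale. What *is* cheap is the image-level diagnosis (here: lung vs
esophageal cancer) and a single click at the tumour centre. `petcam`
implements a weakly supervised pipeline that turns exactly this supervision
-- one class label and one prior point per patient -- into a 3D tumour mask
and an outcome prediction:

1. Two maximum intensity projections (MIPs) summarize the volume: the
   coronal view collapses the anterior-posterior axis `y` (retaining `z`
   rows and `x` columns) and the sagittal view collapses the left-right
   axis `x` (retaining `z` and `y`).
2. A small CNN classifies each MIP by cancer type.
3. A gradient-weighted class activation map (CAM) localizes the class
   evidence, and a *distance constraint* to the projected prior point is
   back-propagated together with the classification loss, pulling the
   evidence onto the tumour rather than onto physiologically avid organs
   (brain, bladder, heart) that also attract the classifier's attention.
4. The two thresholded 2D maps are back-projected and intersected to give
   a 3D mask.
5. A small 3D CNN predicts a binary treatment outcome from a fixed-size
   crop around the segmented tumour.

## The model

### MIP classifier and CAM

The classifier is an eight-layer convolutional network (3x3 kernels, ReLU,
stride-2 downsampling at five layers) mapping a 416 x 160 MIP to a stack of
`D = 128` feature maps `f_i` of size 13 x 5 (a 1/32 stride plan), followed
by dense layers of 128 and 64 elu units with dropout 0.5. The output layer
carries one logit per class (esophagus, lung); the reported probability is
the sigmoid of the logit difference -- numerically the same binary
classifier as a single sigmoid unit, but each class keeps its own linear
readout. That matters for the activation maps: with a single output
vector the two classes' maps are forced to be exact rectified negations
of one another, so one class's evidence map is structurally empty
whenever the network solves the task one-sidedly (which it readily does);
per-class logits let each class develop its own positively weighted
evidence. Both views share one set of weights.

For a class `C`, the CAM is built from the influence of every feature-map
element on the class score,

    w_i^C = (1/N) * sum_{j,z} d yhat^C / d f_i^{j,z},      N = J * Z,
    hmap^C = ReLU( sum_i w_i^C f_i ),

bilinearly upsampled (corner-aligned) to the MIP grid and normalized by its
maximum. [featureInfluence()] differentiates the class probability by
default; the CAM construction differentiates the class's own logit, which
gives the same map up to the normalization but does not vanish when the
classifier saturates.

### The distance constraint

The localization supervision is one voxel `p` per patient, projected into
each view. A loss that merely sums distances between the prior point and
the heat-map *grid* would not depend on the network at all, so the
constraint is the activation-weighted mean distance

    L_distance = sum_i h(q_i) d(q_i, p) / sum_i h(q_i)

over all heat-map pixels `q_i`, in pixel units on the upsampled map. This
is scale-free (normalizing the map changes nothing) and its gradient moves
class evidence toward the prior point. The training objective is

    loss_glob = L_class + alpha * L_distance,     alpha = 1 by default,

with `L_class` the binary cross-entropy of the MIP classification, averaged
over both views of every image in a mini-batch of eight. `alpha = 0` is
exactly the no-prior-knowledge ablation.

### Differentiability choices

The CAM weights `w_i` are themselves gradients; back-propagating through
them exactly would need second derivatives. The training gradient takes
two first-order paths instead: (i) through the feature maps with `w_i`
held constant (the standard treatment of trainable-attention losses), and
(ii) through the head weights that define `w_i`, with the elu-derivative
factors evaluated at the current activations and held constant (an
unrolled first-order approximation). Path (ii) is what allows the head to
*rotate* its readout so that maps active near the prior gain weight --
without it the constraint can only shrink or amplify evidence where it
already is, never relocate it.

Three numerical choices make the constraint trainable in practice, all
acting only on the training objective (the exported loss operations are
unchanged):

* **Diagonal distance units.** Inside training, distances are measured in
  units of the MIP diagonal, putting `L_distance` on the same order as the
  cross-entropy at `alpha = 1`; in raw pixel units the constraint's
  gradients overwhelm classification and training stalls at chance.
* **Mass floor.** An all-zero heat map would trivially score a distance
  loss of zero, making "kill the map" a global optimum -- and training
  does find it. The training objective adds a small uniform mass (1 unit,
  spread over the map) so a collapsed map scores near the *mean* distance
  to the prior instead of zero, and the floor simultaneously bounds the
  `1/mass` factor in the gradient.
* **Leaky rectifier gate.** The gradient of a rectified-away CAM cell is
  zero, so a map whose active cells all sit far from the prior could only
  shrink, never re-form near the tumour. The backward pass passes a
  fraction (0.1) of the gradient through inactive cells.

Even so, the constraint fights the classifier if applied to a freshly
initialized network whose activation maps are noise. The fitting routine
therefore supports `warmupEpochs`: an initial phase trained with the
classification loss only, after which the distance term is switched on
and reshapes an already-meaningful representation. The end-to-end
benchmark warms up for 8 of its 80 epochs.

Segmentation quality under the constraint is not monotone in training
time: the map can drift toward the cohort-mean prior position (a shortcut
that satisfies the *average* distance) and recover again. Neither the
training loss nor the validation global loss tracks this, so the fitting
routine selects its checkpoint by a criterion built from the weak
annotations themselves: the mean 3D distance between the centroid of each
reconstructed validation mask and that patient's prior point
(`valMetric = "maskPrior"`). No ground-truth mask is involved; on
phantoms this criterion tracks held-out dice closely, and
`valMetric = "loss"` remains available.

### 3D reconstruction

Each view's heat map is thresholded at 40% of its maximum (the same
relative level as the clinical metabolic-tumour-volume convention), the
largest connected component is kept, and a voxel `(x, y, z)` is in the
reconstructed mask iff the coronal mask contains `(z, x)` *and* the
sagittal mask contains `(z, y)`. The prism intersection is exact for
axis-aligned cuboids and conservative (a superset) for convex shapes.

The published description of which axes each view retrieves is
self-contradictory between the running text and a figure caption; the
package follows the anatomically consistent reading (a sagittal projection
collapses the left-right axis, so it retains `y` and `z`).

Because the raw CAM grid is roughly 8-32x coarser than the voxel grid, the
prism alone cannot match a voxel-level 40%-of-SUVmax ground truth. The
evaluation harness therefore applies the same clinical rule *inside* the
prism (`refineBySuv()`: keep voxels at or above 40% of the maximum uptake
within the mask). The refinement is idempotent and exposed as an option
(`segmentVolume(refine = )`, off by default at the operation level, on in
the cross-validation harness).

### Outcome network

The outcome classifier is two 3D convolutional layers (3^3 kernels, ReLU),
each followed by 2^3 max pooling, then a dense hidden layer and a sigmoid
unit, applied to a fixed-size crop centred on the mask centroid of the
SUV-normalized volume (48^3 voxels with 32/64 channels by default; 24^3
with 16/32 in the compact configuration). The crop keeps tumour plus
margin by default; zeroing outside the mask is available
(`cropTumor(maskOnly = TRUE)`). The same training routine runs on
physician (ground-truth) masks or on predicted masks, which is how the two
segmentation sources are compared.

## The synthetic phantom

The cohorts the method was designed for are private, so the package ships
a generator whose output has the statistical structure the method assumes:

* a low-uptake body envelope (elliptic cylinder, SUV about 1.5, with
  low-frequency per-patient modulation);
* bright spherical decoys at fixed anatomical-analogue positions ("brain"
  near the top of the volume, "bladder" near the bottom, "heart" left of
  midline), drawn from SUV 8-15 -- often *brighter* than the tumour, which
  is precisely the pathological-vs-physiological confusion the distance
  constraint exists to resolve;
* exactly one anisotropic Gaussian tumour blob per patient (peak SUV 5-12,
  per-axis sigma 2.5-5 voxels), truncated at its bounding cuboid
  (centre +/- 3 sigma). Esophageal tumours sit on the midline column,
  posterior of centre; lung tumours in a lateral lobe, anterior of centre,
  so the cancer type is recoverable from either view -- the classifier has
  something to learn, by construction;
* ground truth by the clinical protocol: the noise-free tumour component
  thresholded at 40% of its maximum inside the bounding cuboid. The prior
  point is the tumour centre voxel and always lies inside the mask;
* additive Gaussian noise (sigma 0.15 SUV, clipped at 0);
* binary outcomes from the `volume_median` rule (1 iff tumour volume above
  the cohort median) with a configurable label-flip probability, 0.1 by
  default, so the outcome net sees a learnable but imperfect signal.

Default volumes are 64 x 64 x 128 voxels at 2 mm, so the MIPs are 128 x 64
and feed the compact classifier configuration without resizing.

What the phantom does *not* emulate: scanner physics (point-spread,
attenuation, reconstruction artifacts), multi-lesion disease, respiratory
motion, inter-scanner intensity shifts, or clinically defined endpoints
(the outcome is a geometric proxy). Passing tests on phantoms therefore
demonstrates the correctness and the internal logic of the machinery --
classification, localization by the constraint, reconstruction, outcome
learning -- not clinical performance on real cohorts.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1 | weight of the distance constraint; 0 = ablation |
| `batchSize` | 8 | images per optimizer step (both views each) |
| `lr` | 1e-4 (`fitMipClassifier`) | Adam learning rate; the phantom-scale experiments use 1e-3 |
| `epochs` | 100 | maximum epochs; early stopping on validation global loss via `patience` |
| `warmupEpochs` | 0 | classification-only epochs before the constraint |
| `relThreshold` | 0.4 | heat-map binarization, relative to map maximum |
| `frac` (`refineBySuv`) | 0.4 | SUV refinement level, relative to SUVmax inside the mask |
| SUV window | [0, 30] -> [0, 1] | fixed intensity normalization |
| resampling | 2 mm isotropic, cubic | spatial normalization (masks: nearest-neighbour) |

## Numerical choices

* Cubic-convolution (Keys, a = -0.5) separable resampling with edge clamp;
  intensities clipped at 0 afterwards (the kernel can undershoot).
* Corner-aligned bilinear CAM upsampling; its transpose is the backward map.
* Cross-entropy probabilities clamped to `[1e-7, 1 - 1e-7]`.
* Zero heat maps: `distanceLoss` returns 0 by convention; `binarizeHeatmap`
  warns and returns an empty mask; dice of two empty masks is 1, of an
  empty vs nonempty mask 0.
* He-scaled Gaussian initialization; Adam (beta 0.9/0.999, eps 1e-8); all
  randomness (initialization, shuffling, dropout, phantom draws) flows
  from explicit integer seeds, and generation is bit-reproducible.
* Normalization order: volumes are SUV-normalized before projection; since
  the map is monotone and applied pixelwise, normalizing before or after
  the maximum gives identical MIPs.

## Problem sizes of the shipped experiments

The test-suite and acceptance-script experiments run the full pipeline at
phantom scale, chosen so the whole suite completes on a single CPU: 60
patients (64 x 64 x 128 voxels), the compact classifier (128 x 64 MIPs,
eight layers with channels 8-64, downsampling by 4 for 32 x 16 x 64
feature maps), 80 epochs (40 for the no-prior ablation, whose objective
converges within about 20 and has no mechanism that improves localization
afterwards) with an 8-epoch warmup at learning rate 1e-3, checkpoint
selection by the mask-centroid-to-prior criterion every 4 epochs,
evaluated on the first of five stratified folds; the outcome net trains
on 24^3 crops (16/32 channels) for 40 epochs on 40 patients and is tested
on 20. The full-size configurations (416 x 160 MIPs, 13 x 5 x 128 feature
maps; 48^3 crops, 32/64 channels) are constructed and shape-checked in
the tests.

The compact configuration keeps the downsampling factor low on purpose:
an activation-map cell must be small relative to the tumour for the
constraint to localize rather than merely re-weight, and at phantom scale
a 4 x 4-pixel cell puts a tumour across several cells. At the full 1/32
plan the 13 x 5 grid plays the same role relative to whole-body
416 x 160 MIPs.

## Seed sensitivity

Both networks are small and trained briefly on small cohorts, so results
vary across generator and training seeds. The constraint's localization
can fail outright for some seeds (the shortcut map wins), and the outcome
task's difficulty depends on how many of a cohort's tumours happen to lie
near the median volume -- binary labels thresholded from a continuum are
intrinsically ambiguous at the boundary, and the network then overfits
the training crops (near-zero training loss, chance-level held-out
accuracy). The shipped experiments state their seeds; they demonstrate
the machinery under the stated conditions, not a seed-uniform guarantee.

## Known limitations

* The reconstruction is limited to one lesion (largest component) and
  axis-aligned view pairs; concave shapes are over-covered by design.
* The distance constraint assumes a single prior point; multiple lesions
  would need one constraint per component.
* First-order CAM training (stop-gradient weights) is an approximation;
  full second-order training is possible in principle but quadratically
  more expensive.
* Training at the full 416 x 160 input size is supported but slow on one
  CPU; the compact configuration is the practical default for simulation
  studies.
* AUC is averaged across folds (not pooled), matching the per-fold
  mean +/- sd reporting convention of the evaluation harness.
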