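# petcam

Weakly supervised 3D tumour segmentation in PET volumes, and treatment
outcome prediction from the segmented tumour — trained from nothing but an
image-level cancer-type label and a single annotated point at the tumour
centre per patient.

## The problem

Radiomic analysis of FDG-PET starts from a 3D tumour segmentation that
normally requires slice-by-slice expert annotation. Image-level labels
(the diagnosis) and a one-click tumour-centre point are cheap. The
difficulty is that a classifier trained on image labels attends to *any*
discriminative uptake — brain, bladder and heart are often brighter than
the tumour — so its class activation maps cannot be used as segmentation
supervision directly.

## The method

For each patient the two orthogonal maximum intensity projections (MIPs)
of the SUV-normalized volume (coronal: rows `z`, cols `x`; sagittal: rows
`z`, cols `y`) are classified by a shared eight-layer CNN. From the last
convolutional layer's feature maps `f_i` (13 × 5 × 128 at the default
input size) a gradient-weighted class activation map is built:

    w_i^C  = (1/N) Σ_{j,z}  ∂ŷ^C / ∂f_i^{j,z}
    hmap^C = ReLU( Σ_i w_i^C f_i )

and upsampled to the MIP grid. Training minimizes the multitask objective

    loss_glob = L_class + α · L_distance ,   α = 1

where `L_class` is the binary cross-entropy of the MIP classification and
`L_distance` is the activation-weighted mean distance between the heat map
and the projected prior point — the term that pulls class evidence onto
the tumour. `α = 0` is exactly the no-prior-knowledge ablation.

At inference the two heat maps are thresholded at 40% of their maximum
(largest connected component kept) and back-projected: voxel `(x, y, z)`
is tumour iff the coronal mask contains `(z, x)` and the sagittal mask
contains `(z, y)`. The evaluation harness additionally applies the
clinical 40%-of-SUVmax rule inside the reconstructed prism. A small 3D
CNN (two conv/pool stages and a dense head) then predicts a binary
outcome from a fixed-size crop around the mask centroid.

Real cohorts of this kind are private, so the package ships a synthetic
phantom generator (body envelope, bright physiological decoys, one
class-dependent Gaussian tumour per patient, 40%-threshold ground truth,
volume-rule outcomes) that reproduces the statistical structure the
method assumes; every stage of the pipeline is tested against it.

## Worked example

```r
library(petcam)

# a 60-patient synthetic cohort: 64 x 64 x 128 voxels at 2 mm, one tumour
# per patient, decoys brighter than the tumour
cohort <- generateCohort(phantomSpec(nPatients = 60, seed = 1))
cohort[[1]]
#> PhantomPatient P001: class esophageal, outcome 0, tumour 253 voxels, prior (34,40,78)

# train the classifier under the multitask objective (8 warmup epochs,
# checkpoint selection by the mask-centroid-to-prior criterion) and
# evaluate the first of five stratified folds end-to-end
rep <- evaluatePipeline(cohort, alpha = 1, config = compactClassifierConfig(),
                        k = 5, maxFolds = 1, seed = 1)
rep$folds
#>   fold      dice       iou classAcc
#> 1    1 0.6468683 0.5005689        1

# the alpha = 0 arm (classification only, no prior knowledge) for the
# ablation comparison
rep0 <- evaluatePipeline(cohort, alpha = 0, config = compactClassifierConfig(),
                         k = 5, maxFolds = 1, epochs = 40, seed = 1)
rep0$folds
#>   fold        dice         iou classAcc
#> 1    1 0.009958471 0.005577427        1
```

`dice` is the voxel overlap `2|A∩B|/(|A|+|B|)` between the reconstructed
and ground-truth masks, `classAcc` the held-out MIP classification
accuracy. Both arms classify perfectly -- the phantom classes are
separable by construction -- but only the distance-constrained arm turns
class evidence into tumour segmentations (mean dice 0.65 vs 0.01): the
unconstrained activation maps settle on physiological decoys, which is
the failure mode the prior point exists to fix.

## Command line

A thin CLI over the package functions is installed at
`inst/scripts/petcam`:

```sh
petcam simulate --n 60 --seed 1 --out cohort/
petcam train    --data cohort/ --out model.rds --alpha 1 --epochs 40
petcam segment  --model model.rds --in cohort/ --out masks/ --refine
petcam evaluate --data cohort/ --out report/
```
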