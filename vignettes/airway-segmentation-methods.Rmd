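---
title: "Methods: memory-efficient 3D U-Net airway segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: memory-efficient 3D U-Net airway segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Segmenting the bronchial tree from a thoracic CT scan is a voxel
classification problem with severe class imbalance (airway lumen is well
under 1% of the scan) and structures spanning two orders of magnitude in
size, from the trachea down to sub-voxel peripheral bronchioles. `airwaynet`
implements an end-to-end convolutional approach: a 3D U-Net trained on large
random patches, with three design commitments that define the method.

**Hybrid padding.** The network uses *valid* (non-padded) 3x3x3 convolutions
in its first `n_valid_levels` resolution levels (default 3 of 5) and
zero-padded convolutions in the deeper levels. Valid convolutions avoid
storing the padded borders of the largest feature maps — the dominant memory
cost in 3D — while the padded deep levels stop the output from shrinking
excessively. The price is bookkeeping: every convolution in a valid level
removes `kernel - 1` voxels per axis, so the output is a centrally cropped
version of the input and skip connections must crop the encoder maps to
match the decoder. `compute_shape_table()` does this algebra symbolically;
`is_admissible_input()` states exactly which input sizes work (all pre-pool
sizes divisible by the pool factor, all skip-crop margins even, all sizes
positive). For the full-size reference network (5 levels, 3 valid, 16
first-level features) an input of 252^3 is admissible and yields a 196^3
output, a margin of 28 voxels per side.

**ROI-masked soft Dice loss.** Training minimizes

    L = 1 - 2 * sum_L(p g) / (sum_L(p) + sum_L(g) + eps)

where the sums run only over the lung-field mask. Masking does two things:
it removes the trachea and proximal main bronchi from the target, focusing
capacity on the hard peripheral branches, and it makes voxels outside the
lungs provably irrelevant to both the loss value and its gradient (a tested
invariant). `eps = 1e-6` defines the empty-ROI/empty-truth limit; it is the
only smoothing applied. Because valid convolutions shrink the output, the
loss compares the prediction against the centrally cropped labels and ROI —
central correspondence is the only alignment consistent with the symmetric
shape algebra.

**Patch pipeline.** Scans are normalized by clipping to [-1000, 500]
(HU-like units) and rescaling to [0, 1], cropped to the lung bounding box
expanded by 30 voxels (the buffer keeps padded-level border effects away
from peripheral airways), and sampled into random patches whose first corner
is uniform over the admissible range. Augmentation applies per-axis flips
(probability 0.5), per-axis rotations uniform in +/-10 degrees, and one
isotropic scale factor uniform in (0.75, 1.25), composed into a single
affine resampling: trilinear for the image, nearest neighbour for labels and
ROI so they stay binary. One interpolation pass avoids compounding
nearest-neighbour artifacts. Regions sampled from outside the source patch
are filled with the parenchyma background value (0.1 normalized) — filling
with 0 would inject large lumen-valued slabs labelled as background, which
measurably degrades the learned boundary. Volumes smaller than the patch
are symmetrically zero-padded before sampling.

## Optimization and convergence

Adam at learning rate 1e-4, batches of one patch, 8 random patches per scan
per epoch, an 80/20 train/validation split made deterministically (sorted
sample ids, seeded shuffle). The convergence rule monitors the moving
average of the validation loss over `ma_window_epochs` and stops when,
relative to its value `stop_patience_epochs` earlier, it rises by more than
5% or fails to fall by more than 0.1%; the returned model is the snapshot at
the overall minimum validation loss. The reference protocol uses a 50-epoch
window with 20-epoch patience; the desk-scale experiment in this package
scales both by one fifth (window 10, patience 4) to match its much shorter
schedule. Validation loss is computed on patches that are random but fixed
per validation scan across epochs (seeded once), giving a stable convergence
signal; the protocol source is silent on this point and a deterministic
choice is the reproducible one.

Weight initialization is Kaiming fan-in scaling with a seed pinned in
`unet_config()`; all other randomness (phantom cohort, split, sampling,
augmentation) derives from named substreams of one master seed, so a fitted
model is bit-reproducible on one platform.

Two architectural points were genuinely open and are pinned as package
design choices, kept configurable: valid convolutions are applied
*symmetrically* in the first levels of both encoder and decoder (symmetric
shape algebra guarantees even skip margins), and upsampling is a learned
2x2x2 transposed convolution that halves the channel count (the most direct
reading of an "upsample layer" with channel halving in the 3D U-Net
lineage); pooling is max pooling.

## Inference and post-processing

Full volumes are processed in a sliding window with 50% overlap per axis.
Each window's probability output occupies the centered sub-window of its
input (the shape-table margins); outputs are accumulated and divided
voxelwise by the number of contributing windows. Because border voxels of
the volume would otherwise never be covered by any output footprint, the
volume is reflect-padded by the network margin before planning — the same
role the 30-voxel bounding-box buffer plays during training. Aggregation is
idempotent in the overlap fraction for a deterministic model (a tested
invariant, tolerance 1e-5).

The binary airway tree is then extracted in four rule-based steps: mask the
probability map to the lung fields; threshold (0.5 by default); merge with a
trachea/main-bronchi mask (the network never sees these regions, since the
loss masks them away); keep the largest connected component. The default
uses 26-connectivity; *EXACT mode* switches to threshold 0.1 with
6-connectivity, compensating for the completeness lost when a single
6-connected structure is required. Equal-size component ties are broken
deterministically (prefer the component containing a central-mask voxel,
else first in scan order).

The lung and central-airway masks come from deliberately simple
region-growing stands-in (`segment_lungs()`: air threshold, border
filtering, morphological closing; `segment_central_airways()`: seeded
26-connected growth with a stepwise threshold schedule and a
volume-explosion guard). They are adequate for phantoms and for testing the
pipeline contracts; clinical-grade lung segmentation is out of scope.

## Evaluation metrics

All metrics operate on centerlines obtained by 3D medial-axis thinning
(topology-preserving directional border peeling with simple-point deletion;
endpoint status is frozen at the start of each sub-iteration, which keeps
transient endpoints created mid-pass from seeding spurious side branches).
With prediction P, ground truth G and ground-truth centerline C:

* tree length detected, `TL = 100 |{x in C : P(x)=1}| / |C|`;
* centerline leakage, `CL = 100 |{x in skel(P) : G(x)=0}| / |C|`;
* false positive rate, `FPR = 100 |P \ G| / |G|` (unbounded above);
* Dice, `DSC = 2|P∩G| / (|P|+|G|)`, defined as 1 when both are empty;
* total tree length in mm: detected centerline voxels times the geometric
  mean of the three voxel sizes.

The trachea and main bronchi are removed from P, G and the centerlines
before scoring, after dilating the exclusion mask by one voxel so skeleton
voxels sitting on the root boundary do not leak into the metrics (the
dilation radius is configurable). Predicted centerlines are computed after
this exclusion, consistent with removing the central airways from "both the
predictions and ground truth". Membership is literal voxel membership in the
binary mask, not membership within a tolerance radius. Every metric is
verified against a brute-force per-voxel loop oracle in the tests.

## The phantom generator

`generate_phantom()` builds the geometry the method assumes, with exact
ground truth and no external data: a binary tree of capsules (cylinders with
spherical caps, rasterized by a distance-to-segment test, which leaves no
gaps at bifurcations) rooted in a vertical trachea analogue entering from
the top slice; radii follow `root_radius * radius_ratio^generation`; a dark
lumen (-1000) inside a brighter wall (-200) against noisy parenchyma (-850,
sigma 25) inside one or two ellipsoidal lung fields, surrounded by
soft-tissue exterior (-200); optional bright vessel-like tubes (+50), always
disjoint from the lumen. The lung field subtracts the root capsule exactly
(un-dilated): the region of interest then excludes the trachea analogue
while the central-airway mask remains adjacent to the in-lung tree, so the
merged segmentation can form a single connected component, as it does on
real scans. Centerlines come from the generative axes, not from thinning, so
the skeletonization operator can be tested against an exact reference, and
the default intensities reproduce the qualitative CT contrast (dark lumen in
brighter wall) without claiming calibrated Hounsfield units.

What the phantom does *not* emulate — and what passing on it therefore does
not show about clinical data: partial-volume effects and reconstruction
kernels, anatomical tapering and lobar structure, breathing or cardiac
motion, pathology (mucus plugging, bronchiectatic dilation), and the
intensity overlap between airway walls and vessels that makes real
peripheral airways hard. The phantom validates the machinery (shapes,
losses, stitching, metrics, optimization), not clinical accuracy.

## The desk-scale reference experiment

`run_phantom_experiment()` is the package's standard end-to-end study, also
recomputed by `scripts/acceptance.R`: 24 phantoms of 64^3 voxels with 4
generations; a reduced U-Net (3 levels, 1 valid, 4 first-level features,
5,891 parameters) on admissible 44^3 patches (output 36^3, margin 4); 19
training / 5 validation phantoms; the standard protocol above with the
scaled convergence windows and a 25-epoch cap. These problem sizes keep a
full run in the tens of minutes on one CPU core while leaving the method
itself unchanged; the full-size configuration differs only in the numbers
fed to the same code paths. Held-out performance is scored with the metrics
above, excluding the root mask.

## Known limitations

* The network stack is implemented natively (direct vectorized convolution
  loops in C++); it is adequate for the reduced experiment but has no GPU
  path, so training the full-size 252^3 configuration is out of reach here.
* `segment_lungs()`/`segment_central_airways()` are intensity stubs tuned to
  phantom-like contrast; real scans need a dedicated lung segmenter.
* Thinning-based centerlines can differ from other skeletonization
  implementations by a few voxels per branch; metric definitions are exact,
  but CL is mildly sensitive to the skeletonizer on fat predictions.
* Training runs single-threaded; batch size 1 is faithful to the protocol
  but leaves vectorization as the only parallelism.
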