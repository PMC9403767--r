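---
title: "Segmenting hypo-enhancing liver lesions with hepaseg: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting hypo-enhancing liver lesions with hepaseg: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Colorectal liver metastases (CRLM) and thermal-ablation zones appear as
hypo-enhancing regions — often with a thin enhancing rim — on portal-venous
contrast-enhanced CT. Radiation and ablation planning both need voxel-wise
segmentations of these regions, and manual contouring is slow. `hepaseg`
implements a complete automatic pipeline: liver-masked preprocessing,
class-balanced sampling of training subvolumes, a family of fully
convolutional 3D segmentation networks including a hybrid 2D–3D dense W-Net,
a staged training protocol, seed-and-threshold post-processing of the
network's probability maps, and lesion-level evaluation. A synthetic liver
phantom makes every stage testable without clinical data.

## Preprocessing

**Intensity normalization.** CT intensities vary across scanners and
contrast timing, and the liver contains high-intensity outliers (vessels,
calcifications) that corrupt a plain mean/standard deviation. `fwhm_stats()`
therefore builds a histogram of the Hounsfield values inside the liver mask
(bin width 1 HU by default, configurable), takes the highest bin as the
center, and converts the full width at half maximum of that peak into a
Gaussian-equivalent scale, `sigma = FWHM / (2 sqrt(2 ln 2))`. The published
description of this step names only the FWHM of the in-liver values; the
histogram-mode reading, the interpolated half-maximum crossings, and the
1 HU bin are this package's concrete choices, and ties at the peak resolve
to the lowest HU. `normalize_in_mask()` standardizes the in-liver voxels
with these statistics and sets everything outside the liver to exactly 0, so
out-of-liver anatomy can never activate the network.

**Resampling.** Images and segmentations are resampled to a common grid
(default 1 mm slices, 0.75 mm in-plane) with trilinear interpolation; output
sizes follow `round(n * s_old / s_new)` per axis, with a minimum of one
voxel. Ground-truth masks are interpolated linearly and thresholded at 0.5,
mirroring how the images are treated; predictions are mapped back to each
patient's original grid with nearest-neighbor interpolation before any
metric is computed. Disease labels outside the liver mask are clipped to the
liver with a warning — the model input is liver-masked, so such labels are
untrainable.

## Class-balanced slabs

Training on whole livers lets a network reach low loss by predicting
"normal" everywhere, because almost all voxels are normal liver, and
per-class weights would instead over-weight patients with bulky disease.
`extract_slabs()` therefore cuts one fixed-size subvolume (default
32 × 120 × 120 voxels) per connected disease site, centered on the site
centroid. Windows are shifted inward at volume boundaries, sites larger than
the window are covered by `ceiling(extent / window)` tiles with minimal
overlap, and a slab's label contains *every* disease voxel inside the
window, not only the seeding site. The union of all slab labels therefore
covers the full ground truth — a property the test suite asserts on random
phantoms. Augmentation is restricted to axis flips/mirrors applied
identically to image, liver and label, with per-axis probability 0.5 on the
fly. Whether healthy-only slabs should complement the disease-seeded ones is
left open by the source description; this implementation emits only
disease-seeded slabs.

## Architectures

Four families are built from one declarative graph representation
(`build_unet3d()`, `build_hybrid_wnet()`):

* **Standard 3D U-Net** — encoder-decoder with max pooling (factor 2 per
  axis), skip concatenation between matching levels, and
  3 × 3 × 3 convolution + batch normalization + ReLU blocks. Filters double
  after each pooling up to a cap; block counts may grow per level (the
  "convolution lambda", exposed as `conv_block_increase`).
* **Residual 3D U-Net** — block inputs are added to the convolution output
  before activation; a 1 × 1 × 1 projection reconciles channel counts when
  they differ.
* **Dense 3D U-Net** — each convolution in a level receives the
  concatenation of all previous outputs of that level. With a positive
  `growth_rate` every dense convolution emits `growth_rate` channels (so
  concatenated inputs grow linearly at that slope); with growth 0 it emits
  the level's filter count.
* **Hybrid W-Net** — a 2D U-Net whose encoder is the DenseNet-121 topology
  applied slice-wise, decoded back to full resolution into 32 feature maps
  per slice, concatenated with the image and liver-mask channels as input to
  a 3D dense network. The 3D dense connections are *global*: every
  convolution at a spatial scale sees all previous same-scale outputs from
  encoder and decoder alike, which is what lets the 3D part stay very small
  (eight initial filters).

The graph is also the unit of parameter accounting: a convolution holds
`prod(kernel) * c_in * c_out (+ c_out if biased)` weights and a
batch-normalization layer `4 * channels`, of which the two running
statistics per channel are never trainable. `count_parameters()` computes
these counts in closed form, and `instantiate_network()` allocates weights
that match them exactly — the test suite verifies the equality weight-for-
weight across all four styles.

Three details of the full-size hybrid are not fixed by its published
description and were settled here once:

* The published figure gives the 3D network eight initial filters with two
  and three convolution blocks on its two layers, while the results prose
  says "32 filters" with a convolution lambda of two. Both readings are
  constructible (`hybrid_wnet_config("figure")` / `"results"`); the figure
  reading is the package default.
* The 2D decoder is unspecified. The package uses one upsampling stage per
  DenseNet-121 downsampling stage, skip concatenation from the matching
  encoder stage, two 3 × 3 convolution + batch-norm blocks per stage and a
  channel schedule of 256/128/64/32 ending in the 32 output features, plus
  the auxiliary two-class head used when the 2D network trains standalone.
* DenseNet-121 expects three input channels; the single normalized-CT
  channel is replicated three-fold (the liver mask enters the 3D network
  only), which would preserve pretrained first-layer weights where such
  weights are supplied.

Under these choices the full builds hold 13,784,036 parameters (figure
reading; 13,698,180 trainable) or 14,986,564 (results reading; 14,900,100
trainable). The two readings bracket the originally reported total of
14,497,600 at −4.9% and +3.4% respectively; since the non-trainable count
pins the decoder's batch-norm channels tightly, no natural decoder
reconstruction examined here reproduces the printed counts exactly, and the
residual is reported rather than hidden. The DenseNet-121 encoder itself
matches its reference implementation's counts exactly (7,037,504 total,
83,648 non-trainable).

No deep-learning framework is available to R in this package's dependency
set, so the forward/backward engine behind these graphs (convolution via
blocked shifted-GEMM, batch normalization, pooling, nearest-neighbor
upsampling, softmax cross-entropy, Adam) is implemented in the package with
Rcpp/RcppArmadillo kernels. Networks accept variable spatial sizes: inputs
are reflect-padded to the graph's pooling multiple and outputs cropped back,
so whole livers can be evaluated in one pass while training uses slabs.

## Staged training

The hybrid model trains in four ordered phases, each freezing what earlier
phases learned: (1) only the new 2D decoder (pretrained or previously
trained encoder frozen), (2) the full 2D network, (3) only the 3D network on
the frozen 2D features, (4) end to end. Freezing makes high learning rates
safe — without it, the first steps of each stage visibly untrain their
predecessors. Frozen groups are bit-identical before and after a phase
(asserted in the tests); frozen batch-normalization layers also run in
inference mode so their running statistics stay untouched.

Each phase uses a triangular cyclical learning rate. Its bounds come from an
exponential range sweep on a throwaway copy of the model: the largest rate
before the loss exceeds 1.2 × the running minimum of the smoothed
(factor 0.98) trace becomes `lr_max`, and `lr_min = lr_max / 10`. Two
implementation details matter at the short sweep lengths used on CPU: the
loss observed at a step reflects the *previous* step's update, so losses are
paired with the rate that produced them (one trailing forward pass closes
the sweep), and divergence is detected on the instantaneous loss rather than
the heavily lagged smoothed trace. The sweep ceiling defaults to 0.02, a
conservative ceiling for the adaptive-moment optimizer; on this task larger
rates do not diverge visibly — they collapse the model onto the majority
class, which a loss-based finder cannot see.

Batch normalization uses a running-statistics momentum of 0.9 so that
inference statistics are usable after the short phases this package targets;
training losses are optimized with Adam at framework-default moments
(0.9/0.999, epsilon 1e-7). Epoch budgets and early stopping (patience 5
evaluations without validation improvement) are pragmatic defaults — the
source protocol does not state them. Validation during training is the
patient-wise mean Dice on whole livers at training resolution, evaluated
through the output head the phase optimizes (the auxiliary 2D head during
the 2D phases); each model is trained from three random restarts by default
and selected on validation Dice, ties resolving to the lowest seed.

## Post-processing

Network probabilities are highest in lesion centers and fall off toward the
most inferior/superior slices. Plain thresholding either clips those ends or
floods noise, so the final mask is grown: voxels with probability at or
above a *seed* level anchor components, which then expand through the
connected region at or above a lower *threshold* (default connectivity 26).
The shipped operating point, seed 0.67 / threshold 0.30, is the published
tuned value; `tune_seed_threshold()` reproduces the tuning by exhaustive
search over seeds 0.25–0.95 and thresholds 0.20–0.80 in 0.01 steps (pairs
with seed < threshold are skipped as invalid), maximizing mean patient Dice
by default — whether the original tuning objective was patient-mean or
global Dice is not stated, and the global variant is available via a flag.
Ties resolve to the smallest seed, then the smallest threshold.

## Evaluation

All metrics run at original image resolution. Per patient: Dice, median
surface distance (face-adjacent boundary voxels, symmetric pooled
nearest-surface distances in mm, median; undefined — not zero — when a mask
is empty), and the false-positive decomposition: predicted components with
zero ground-truth overlap are "erroneous" volume (their count is the
false-positive discoveries), and the remaining predicted-outside-truth
voxels are over-segmentation, so the two sum exactly to the false-positive
volume. Per site: each connected ground-truth component is matched to the
predicted component with the nearest centroid (a prediction may serve
several sites); site Dice and surface distance use the matched component
only, while detection uses the union of all predictions with an inclusive
45% overlap criterion. Cohort level: global Dice stacks all patients before
the ratio, and the site table stratifies by sphere-equivalent diameter
`(6V/pi)^(1/3)` (bins default to <15 mm versus ≥15 mm). Empty-versus-empty
masks score Dice 1, empty-versus-nonempty 0. The diameter definition and
the symmetric (rather than one-directional) surface distance are this
package's readings of an underspecified description.

## The phantom: what it does and does not show

`generate_phantom()` builds an ellipsoidal liver at a parenchymal mean
(default 100 HU) with spherical hypo-dense lesions (core offset −40 HU,
optional +30 HU rim), additive Gaussian noise (default 15 HU) and air
background; masks are exact. These defaults are plausible portal-venous
values chosen once for testability — they are not fitted to any dataset.
`synth_probability_map()` stands in for model output by blurring the
disease indicator (2 mm Gaussian) and adding clipped noise; at the shipped
operating point this recovers lesions of roughly 16 mm and larger at Dice
above 0.9, with the margin growing with lesion size, because the 0.30
growth threshold sits about half a blur-sigma outside a large lesion's
boundary while the relative bias shrinks with diameter.

Passing the phantom suite shows the pipeline's plumbing, geometry and
optimization behave as specified. It does not show clinical performance:
real CRLM have irregular shapes, partial-volume and motion effects,
heterogeneous enhancement, confounding vessels and bile ducts, and much
larger volumes — none of which the phantom models. The published
full-scale accuracies require the public challenge datasets and GPU-scale
training and are out of scope here.

## Problem sizes used by the test suite

The reference slab size is 32 × 120 × 120 voxels, and all operations accept
it; the shipped tests exercise the same code paths at reduced sizes chosen
as the package's own test design — phantoms of 16 × 48 × 48 voxels at
2 × 1.5 × 1.5 mm, slabs down to 12 × 40 × 40, a hybrid model with a small
plain 2D encoder (`encoder2d = "simple"`, four initial filters, eight 2D
feature channels), batch sizes 1–2 against the reference 8–16, and staged
phases of 6–30 steps. Under these conditions the end-to-end recovery
property (train on 16 phantoms, predict and grow on 20, mean patient Dice
≥ 0.7) and the single-slab overfit property (Dice > 0.8 within 200 steps)
hold with margin; both are seeded and stochastic.

## Known limitations

* The engine is CPU-bound and double-precision; it is built for correctness
  and desk-scale experiments, not for training at the published scale.
  Mixed precision is not implemented.
* ImageNet-pretrained DenseNet-121 weights are not bundled; instantiation
  is random unless a checkpoint file is supplied explicitly, so transfer
  from natural images — one motivation of the hybrid design — is not
  reproduced, only its architecture and training protocol.
* DICOM series are not read; convert to NIfTI first.
* The exact 2D decoder of the original hybrid model is unknown; parameter
  totals carry the documented residual against the published count.
* Seed-and-threshold growth is the only post-processing; no morphological
  smoothing, hole filling or CRF refinement.
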