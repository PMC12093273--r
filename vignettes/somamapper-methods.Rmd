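---
title: "Methods: brain-wide soma detection and mapping with somamapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-wide soma detection and mapping with somamapper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

somamapper detects fluorescently labeled neuronal somata in whole-brain 3D
light-microscopy volumes and maps them onto brain-atlas regions. The pipeline
has four stages: preprocessing (isotropic resampling, sub-block partition,
per-block maximum intensity projection), a lightweight residual 2D classifier
that gates soma-containing blocks, a 3D segmentation network with a
shifted-window self-attention bottleneck, and connected-component detection
followed by atlas-region assignment with whole-brain-normalized counts. This
vignette records the models, the parameters that matter, and the design
decisions behind the implementation.

## The synthetic phantom: what it emulates, and what it does not

Real whole-brain fluorescence volumes of retrogradely labeled neurons are
terabyte-scale and not redistributable, so the package carries a seeded
phantom generator (`phantom_spec()`, `generate_phantom()`) whose samples are
the substrate for every test and for the acceptance script. A phantom
emulates the regimes that make soma detection hard in practice:

* **sphere-like somata** of varying radius and peak brightness (defaults:
  radius 3–6 voxels, intensity 0.4–1.0), rendered as hard balls
  (`‖p − c‖ ≤ r`) with a 1-voxel raised-cosine intensity rolloff. The
  ground-truth mask is the binary ball — matching the convention that manual
  annotation is binary — while the rolloff keeps rendered edges soft;
* **touching soma pairs** (`overlap_fraction`): partners are placed at
  distance `1.2 (r₁ + r₂)/2`, close enough that their masks touch or merge,
  which is the known failure regime of connected-component detection;
* **soma-mimicking background speckles** (`n_noise_blobs`): rendered blobs
  strictly smaller than the minimum soma radius that appear in the image but
  never in the mask — the background clutter that the gating classifier must
  reject;
* **uneven illumination**: a multiplicative linear ramp along x from
  `1 − g` to 1; and **sensor noise**: additive Gaussian with `noise_sigma`,
  after which intensities are clipped to `[0, 1]`.

Soma centers are drawn at integer voxel centers; all random choices come
from one RNG stream per seed in a documented order (pairs first, then
singles, each soma drawing radius, intensity, placement; then noise blobs;
then the noise field), so a spec is bit-reproducible. Placement retries are
bounded; a spec whose somata cannot be placed raises an "overcrowded" error
rather than silently truncating.

The phantom deliberately omits optics (no PSF convolution), vasculature,
fibers-of-passage, and stitching artifacts. Passing tests on phantoms
therefore demonstrate the correctness of the pipeline's machinery and the
trainability of the networks on separable data — not performance on real
fMOST-grade material, whose soma density and SNR are not quantified in a way
we could calibrate to.

## Preprocessing

Raw acquisitions are anisotropic (e.g. 0.35 × 0.35 × 2 µm).
`resample_isotropic()` brings them to a uniform grid by separable cubic
spline interpolation with center-aligned coordinates, so resampling at the
native voxel size is an exact identity; each output dimension is
`round(dim × voxel/target)`, and interpolation overshoot is clipped back to
the input range. Volumes with any dimension below 4 voxels are rejected
(cubic support). `partition()` tiles the volume into non-overlapping blocks
(production default 512³; the tests use 32–64³) and zero-pads edge blocks so
every block presents the same shape to the networks; `mip()` projects the
per-voxel maximum along z (the sectioning axis) by default. Intensity
normalization is global min–max at load time.

## The gating classifier

`build_classifier()` constructs a deliberately small residual 2D network: a
stem conv lifting 1 channel to `stem_channels`, then four stages of
`conv3×3 → BN → ReLU → conv3×3 (stride 2) → BN` with a
`conv1×1 (stride 2) → BN` projection shortcut, added and passed through
ReLU. All downsampling is by stride-2 convolution — there is no max pooling
anywhere — followed by global average pooling, one fully connected layer,
and a softmax over {background, soma}. Default stage widths are
(16, 32, 64, 128) with stem 16; these are configurable, and even the default
is far below an 18-layer residual reference (`resnet18_param_count()` gives
the yardstick: ~11.2 M parameters vs ~0.31 M at the default widths).

Training (`train_classifier()`) is plain SGD, default learning rate 1e-4
and batch size 8, up to 100 epochs. After every epoch the validation AUC is
computed by the rank (Mann–Whitney) formulation; "no significant
improvement" is a gain of at most `min_delta = 1e-4` over the running best,
and training halts after `patience = 10` consecutive epochs without one.
Two implementation choices matter here:

* **Batch-norm recalibration.** With small minibatches the running BN
  statistics lag behind the weights, which mis-calibrates inference-mode
  probabilities even when the ranking (AUC) is perfect. Before every
  validation pass — and therefore in every saved checkpoint — the running
  statistics are recomputed exactly (momentum 1) on a fixed calibration
  batch of training images.
* **Checkpoint tie-breaking.** Among epochs that tie the best validation
  AUC, the latest is kept: the training loss keeps falling while the AUC is
  saturated, which improves the calibration of the returned checkpoint. The
  patience clock is unaffected (it resets only on significant improvement),
  so the stopping arithmetic is unchanged: a constant metric stops training
  at epoch `patience + 1`.

MIPs are padded (and, if larger, cubically downscaled) to a fixed square
input resolution, 512 by default, 32 in the tests; the resolution must be
divisible by 2⁴ for the four stride-2 stages. The decision threshold on the
soma-class probability is 0.5.

## The 3D segmentation network

`build_segmenter()` follows an encoder–bottleneck–decoder layout with `K`
channels throughout (default 16; 8 in the smoke-scale runs):

* **encoder** — stem conv (1 → K); stage 1: one conv encoder block then a
  stride-2 conv (to 1/2); stages 2 and 3: two encoder blocks plus a stride-2
  conv each (to 1/4, then 1/8); stage 4: four encoder blocks at 1/8 with no
  downsampling. Every conv is 3×3×3 with batch norm and ReLU.
* **bottleneck** — `L` (default 1) Video Swin transformer blocks. Each
  block is two attention sub-layers with pre-norm residuals: plain windowed
  multi-head self-attention (W-MSA) over non-overlapping `ΔH×ΔW×ΔD`
  windows, then the shifted variant (SW-MSA) whose features are cyclically
  shifted by half a window per axis before windowing, with an additive mask
  (−10⁹ on the logits) so tokens from opposite sides of the cyclic wrap do
  not attend to each other; each attention sub-layer is followed by a
  GELU feed-forward network with expansion `ffn_ratio = 4`. A learned
  relative-position bias per window offset is on by default (configurable
  off). When the window equals the feature extent along an axis, the shift
  is disabled on that axis — full-extent attention already connects every
  pair of tokens, and shifting would only introduce spurious masking.
* **decoder** — two convs at 1/8, then three upsampling stages. Upsampling
  is a 2×2×2 transposed convolution; each stage concatenates the matching
  encoder output as a skip connection (at 1/4, 1/2, and full resolution) and
  convolves 2K → K. A final 1×1×1 conv and sigmoid produce the probability
  map, binarized at 0.5.

One bookkeeping note: the encoder description that inspired this layout
jumps from H/2 to H/8 across its middle stages, leaving the 1/4 level
implicit. We use the standard 1/2 → 1/4 → 1/8 ladder and tap the skips at
full, 1/2, and 1/4 resolution — the three levels the three decoder stages
actually consume.

Training (`train_segmenter()`) uses Adam at 1e-4, decayed by 10% every 10
epochs (`lr_at_epoch()`; e.g. 8.1e-5 during epoch 25), batch size 1, up to
200 epochs of 80 iterations, soft Dice loss
`1 − (2Σpt + ε)/(Σp + Σt + ε)` with `ε = 1e-5`, and augmentation by a
random crop (default 128, divisible by 8) plus left-right and up-down flips
at probability 0.5 each, applied identically to image and label. Validation
Dice (binarized) is monitored with patience 30; BN recalibration and
checkpoint tie-breaking work exactly as for the classifier.

All layers — convolutions via im2col + BLAS GEMM in compiled code, batch
norm, layer norm, windowed attention, transposed convolutions — carry
hand-derived analytic gradients, verified against central finite differences
during development; the window partition/reverse and cyclic shift/unshift
pairs are exact inverses by construction and are tested at bit level.

## Inference on large volumes

`plan_patches()` zero-pads a volume so that overlapping patches (default
128³ with stride 64³; pre-condition `stride ≤ patch`) tile it completely,
with patch origins at all multiples of the stride. `segment_volume()`
accumulates per-patch probabilities into a full-size buffer and **averages**
overlapping voxels — averaging is order-invariant, unlike last-write-wins —
then crops the padding and binarizes. `resample_for_inference()` applies
per-axis scale factors (cubic) and records them so detections map back to
original coordinates via the inverse center-aligned transform.

## Detection and matching

`connected_components()` labels foreground regions under 6/18/26
connectivity; the default is 26, because diagonal touching is exactly how
closely adjacent somata merge in segmentation output. `centroids()` takes
the geometric center (mean member-voxel coordinate, 0-based) of each
component as the soma location. Components touching block faces are handled
by `detect_in_blocks()`, which stitches per-block masks into the parent
volume before labeling, so a soma straddling a block boundary yields one
detection instead of two.

`match_points()` compares detections with ground truth: candidate pairs are
all pairs within the threshold (default 10 pixels, the average soma radius
at the working resolution; a distance of exactly 10.0 counts as a match),
accepted greedily in ascending distance with each point used at most once
and ties broken by lower (gt, pred) index. On detection-like geometry —
ground-truth points separated by more than twice the threshold — this greedy
rule coincides with the exhaustive minimum-weight maximum-cardinality
assignment, which is what the test suite verifies by brute force on
instances of up to six points per side. No splitting of merged adjacent
somata is attempted; that is a stated limitation of connected-component
detection.

## Evaluation metrics

`classification_metrics()` computes accuracy, sensitivity, and specificity
from confusion counts, raising on zero denominators rather than returning a
silent 0; `auc()` is the rank formulation with ties counted one half.
`dice()` is `2|A∩B|/(|A|+|B|)` with two documented conventions: empty vs
empty is 1, empty vs non-empty is 0. `avg_euclidean_distance()` averages
over matched pairs only and raises when there are none — an average over no
matches is undefined, not 0 or ∞.

`detection_metrics()` exposes **two conventions**. The literature this
package follows defines precision = NTP/NGT and recall = NTP/Ndetected —
note these swap the conventional denominators. Rather than guessing whether
that is intended, the package computes the formulas as printed under
`convention = "as_printed"` (the default) and the textbook assignment under
`"conventional"`. F1, being the harmonic mean, is identical either way.

## Atlas mapping

Registration itself is out of scope — it is performed by external tools —
so `point_transform()` consumes an exported invertible 4×4 affine plus an
optional dense displacement field, applied as `p′ = Ap` then
`p′ += D(p′)`. `assign_regions()` floors each transformed point to its
containing atlas voxel; points outside the grid, on the max face, or on
label 0 are reported unassigned, never silently dropped into a region.
`region_fractions()` divides each region's count by the total assigned
count (fractions sum to 1 whenever the total is positive; unassigned points
are excluded from the total and reported separately), and an optional
midline plane adds per-hemisphere counts for ipsi/contra analyses.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at smoke scale,
chosen as the smallest sizes at which each behavior is observable:
32–64-voxel phantoms, classifier input 32², stem 8, segmenter K = 8 with
crop 32 and window 2³, 20–30 epochs with 8 iterations per epoch and learning
rates raised accordingly (0.02–0.1 SGD, 1e-3 Adam). Production defaults (512³
blocks, input 512², K = 16, crop 128, 80 iterations, production-scale
learning rates) are the configuration defaults. Other fixed numerical choices:
dice-loss smoothing 1e-5, BN epsilon 1e-5, attention logits scaled by
`1/√(K/heads)` with a numerically stabilized softmax, early-stopping
`min_delta` 1e-4, sigmoid binarization at 0.5.

## Known limitations

* Adjacent somata closer than the phantom's pairing distance merge into one
  component; no watershed-style splitting is attempted.
* The phantom is an idealization; performance numbers on it say nothing
  quantitative about real tissue.
* Volume I/O is multi-page TIFF and CSV/JSON; the atlas grid is consumed as
  an integer array rather than any specific atlas file format.
* Training is CPU-bound and single-threaded BLAS-scale; the architecture is
  faithful at reduced width, not a performance-parity reimplementation.
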