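---
title: "Coarse-to-fine mandible segmentation: model, training and evaluation"
author: "c2fseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine mandible segmentation: model, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c2fseg)
```

## The problem

Cone-beam CT (CBCT) is the standard modality for orthodontic and
orthognathic 3D planning, but its low dose brings heavy noise, and the
metallic objects common in these patients — braces, fillings, implants —
radiate bright/dark streaks across the axial plane that destroy the true
bone boundary. Segmenting the mandible (body, rami, condyles, teeth
region) from such scans is the bottleneck step: thresholds and shape
models fail near artifacts, and plain slice- or patch-wise CNNs either
oversegment the teeth region (where upper and lower jaw fuse behind
streaks) or miss the weakly contrasted condyles.

`c2fseg` implements a two-stage *coarse-to-fine* decomposition of this
task, in the spirit of curriculum learning: first solve the easy problem
(where, roughly, is the mandible-like structure in the whole volume?),
then the hard one (which voxels exactly are mandible?), letting the first
answer constrain the second.

## The two-stage model

Write $X \in \mathbb{R}^{n \times w \times h}$ for the scan,
$Y \in \{0,1\}^{n \times w \times h}$ for the ground truth, and
$\hat Y = F(X, \theta)$ for a segmentation operator. The cascade is

$$\hat Y = F_2(F_1(X, \theta_1), X, \theta_2),$$

with the two stages trained separately on the same objective.

**Coarse stage $F_1$** — a 3D *SegUnet*: an encoder–decoder CNN that
combines two kinds of cross connection. Each of the `depth` encoder
blocks is (conv $3^3$ → batch norm → ReLU) ×2 followed by $2^3$ max
pooling that *records its argmax coordinates*; each decoder block first
max-unpools its input using exactly those recorded coordinates
(SegNet-style index transfer), then concatenates the same-level encoder
features (U-Net-style skip), then applies two conv–BN–ReLU layers. Filter
counts start at `baseFilters` and double per level; a 1×1×1 convolution
plus sigmoid produces the voxelwise foreground probability. The decoder's
second convolution halves the width so the channel count entering the
next unpooling always matches the recorded indices of that level.

Because whole head-and-neck volumes do not fit through a 3D network, the
coarse stage is patch-based: training samples sub-volumes (reference size
$64 \times 128 \times 128$), and inference slides a window with a small
overlap over the full volume, averaging the per-window probabilities
voxelwise (`tileVolume()` / `fusePatches()`). The last window per axis is
clamped to the volume boundary so every voxel is covered.

**Fine stage $F_2$** — a *recurrent* 2D SegUnet with the same block
structure (2D kernels). It walks the axial slices in ascending order;
step $t$ receives the 3-channel stack

$$(x_t,\ \hat y^{1}_t,\ \hat y^{2}_{t-1})$$

— the image slice, the coarse probability slice, and the previous slice's
own prediction — and outputs $\hat y^2_t$. The recurrence carries the
anatomical continuity of the mandible across slices, which is what
rescues weak condyle/ramus boundaries, while the coarse channel keeps the
network from wandering into artifact-created false structures.

## Objective and gradient

Both stages minimize the compound loss

$$L = \omega_1 L_{BCE} + \omega_2 L_{Dice}, \qquad
\omega_1 = \omega_2 = 0.5,$$

with $L_{BCE}$ the mean binary cross-entropy and
$L_{Dice} = 1 - (2\sum y\hat y + s)/(\sum y + \sum \hat y + s)$. The BCE
term penalizes false positives and false negatives voxelwise; the Dice
term directly optimizes the overlap that evaluation measures and copes
with the extreme foreground/background imbalance. The package implements
the analytic per-voxel gradient of this loss (`lossGradient()`) and uses
it as the quantity backpropagated into the network; it is verified in the
test suite against central finite differences (rel. err < 1e-4) and a
fourth-order Richardson difference oracle (rel. err < 1e-6).

During fine-stage training the per-slice losses $L_t$ are summed and
gradients flow backwards through the recurrence (backpropagation through
time), truncated to windows of `bpttWindow` slices (default 4, one Adam
update per window). Two reconciliations the recurrence needs:

* the previous-slice channel is fed the *soft* probability during
  training, so gradients can flow through it; binarization happens only
  at the end of inference;
* the prediction "before" the first slice is an all-zeros map (an
  alternative — seeding with the coarse slice — is a config switch).

Whether to feed the model's own previous prediction or the ground truth
of slice $t-1$ (teacher forcing) during training is genuinely open; the
default is the model's own soft prediction, which matches the inference
regime, and `teacherForcing = TRUE` exposes the alternative.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| intensity bounds | $[-1000, 2000]$ | raw values are clipped here and mapped to $[0,1]$; applied identically to CBCT-like data whose stored values are not calibrated HU |
| `baseFilters`, `depth` | 32, 4 | reference architecture; desk-scale runs use 4, 2 |
| patch size | $64\times128\times128$ | training sub-volume and sliding window; desk scale $16\times32\times32$ |
| overlap | $(8,16,16)$ | sliding-window overlap ("small" relative to the patch); fusion is the voxelwise arithmetic mean |
| `positiveFraction` | 0.5 | probability a training patch is forced to cover foreground; the uniform remainder is hard negative mining |
| $\omega_1, \omega_2$ | 0.5, 0.5 | loss weights |
| learning rate | $10^{-4}$ | Adam, reference config; the desk-scale study uses $10^{-3}$ for its far smaller nets and data |
| `bpttWindow` | 4 | BPTT truncation length (bounded memory; window 1 = detached per-slice training) |
| threshold | 0.5 | final binarization; ties map to foreground |

Dice smoothing $s = 10^{-6}$ and BCE clipping $\varepsilon = 10^{-7}$
stabilize empty masks and saturated sigmoids. Max pooling breaks ties to
the first maximum in scan order; weight init is Kaiming fan-in, BN
$\gamma = 1, \beta = 0$, running statistics with momentum 0.1.

## Evaluation metrics

`evaluateCase()` reports, per case and in physical millimetres (voxel
index × spacing):

* **Dice** $= 2|A \cap B| / (|A| + |B|)$, 1 for two empty masks;
* **ASD**, the symmetric mean of nearest-boundary distances
  $[d(A,B) + d(B,A)]/2$, $d(A,B) = |A|^{-1}\sum_a \min_b \|a-b\|$;
* **HD** and **95HD**: the directed distance takes the nearest-rank
  percentile ($\lceil p\,|A|\rceil$-th of the ascending nearest-neighbor
  distances, $p = 1$ or $0.95$), and the symmetric value is the larger of
  the two directions. The 95th percentile discounts a small fraction of
  outlier boundary points.

The boundary of a mask is defined as its foreground voxels with at least
one background 6-neighbor (out-of-volume counts as background), and
distances run between voxel centers. The percentile uses the nearest-rank
rule so small point sets have unambiguous values. These conventions are
frozen so the brute-force oracles in the test suite match to 1e-9. When
exactly one mask is empty the distances are undefined and reported as
`NA` with a warning rather than infinity, keeping report tables finite.

## The synthetic phantom

No clinical data ships with the package; `generatePhantom()` builds a
mandible-like phantom instead: an axial horseshoe arch (annulus with a
posterior opening) over a band of slices, two rami rising from the arch
ends, condylar knobs on top; bone at 1200 over tissue at 0 on a CT-like
scale. Artifacts mimic the metal problem: a few "tooth" voxels at 3000 —
deliberately above the 2000 clip ceiling, so they saturate exactly as
real fillings do — plus, per metal voxel, random-angle in-plane rays with
alternating ±400 offsets and linear falloff (bright/dark streaks), plus
Gaussian noise (SD 50). Labels cover the anatomy including the metal
voxels (teeth belong to the mandible in the gold standard) and are by
construction independent of the artifact settings.

What the phantom does *not* emulate: beam-hardening physics, scatter,
anatomical shape variation, neighboring bones (skull base, hyoid,
vertebrae), or CBCT's intensity non-uniformity. Passing the desk-scale
study therefore shows that the pipeline's mechanics — sampling, two-stage
training, BPTT, sliding-window fusion, recurrence, metrics — work and
that the cascade can learn to ignore streak artifacts; it does not
predict clinical accuracy on real scans, which is reported in the
literature from private CBCT/CT cohorts.

## The desk-scale study

`runCascadeStudy()` fixes the package's reference experiment at sizes a
single CPU handles in a few minutes: 20 training + 5 held-out phantoms of
$32 \times 64 \times 64$ voxels with artifacts enabled; coarse net with
`baseFilters` 4, `depth` 2 trained 30 epochs on $16\times32\times32$
patches (one per case per epoch, Adam $10^{-3}$); fine net trained 15
epochs with BPTT window 4. Every random draw derives from one master
seed, and repeated runs reproduce bit-identically in single-threaded
execution. The held-out evaluation reports the thresholded coarse-only
prediction next to the full cascade (with largest-26-connected-component
post-processing), so the refinement stage's contribution is measured
rather than assumed. `scripts/acceptance.R` is a thin wrapper around this
function.

## Known limitations

* The conv-net engine is purpose-built for this architecture (direct C++
  convolutions, manual backprop); it supports exactly the SegUnet family
  described here, not arbitrary graphs, and runs on CPU only — the
  reference-scale configuration (base 32, depth 4, $64\times128\times128$
  patches) is expressible but impractical without days of CPU time.
* Batch normalization with the effective batch size of one patch/slice
  behaves like instance normalization during training; running statistics
  make inference deterministic.
* Fusion weights overlapping windows uniformly; Gaussian-weighted fusion
  is out of scope.
* The recurrence is single-direction (ascending slices); reversing the
  order may change outputs, and no bidirectional averaging is attempted.
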