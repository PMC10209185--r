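---
title: "Methods: multi-class tissue segmentation and biopsy risk classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-class tissue segmentation and biopsy risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Colorectal cancer diagnosis starts from H&E-stained biopsy and polyp
sections. Two tasks dominate the routine workload: recognizing *which
tissue compartments* are present (glands, dysplastic epithelium, stroma
variants, mucus, necrosis, immune infiltrate, ...) and condensing those
findings into a *slide-level risk category* that drives clinical follow-up.
`crcseg` implements a two-stage pipeline for both tasks:

1. a convolutional encoder-decoder that segments RGB tiles into **14
   tissue classes** (indices 0-13, `tissue_schema()`), trainable under
   four interchangeable objectives — categorical cross-entropy, focal
   loss, bi-tempered logistic loss, and the Lovász-softmax surrogate of
   the Jaccard index;
2. a **random forest** that converts slide-level segmentation maps into
   one of four ordinal risk categories
   (`other < hyperplasia < low_grade_dysplasia < high_risk`) from 18
   interpretable features per tissue fragment.

Everything runs offline: a synthetic-data module generates textured tiles
with paired masks and labelled slide cohorts, so the full pipeline can be
trained, evaluated and tested without any external imaging data.

## The segmentation model

The network (`unet_spec()`, `unet_build()`) is a U-Net variant:

* 32 base filters, doubled after each of 4 max-pooling levels
  (32-64-128-256-512 at the bottleneck);
* each block consists of two same-padded 3×3 convolutions with batch
  normalization and ReLU, and the block's **input is concatenated onto its
  last feature map** before pooling — a ResNet-inspired intra-block skip
  that improves gradient flow;
* the decoder replaces transposed convolutions with **nearest-neighbor
  upsampling followed by a 2×2 convolution**, avoiding checkerboard
  artifacts;
* weights use fan-in-scaled Gaussian initialization (`sd = sqrt(2/fan_in)`,
  the scheme designed for rectifiers), and a 1×1 head produces 14
  softmax-normalized likelihood maps aligned with the input grid.

Design points that were genuinely open and how they were resolved:

* **Depth and block internals.** Four pooling levels with two 3×3
  convolutions per block mirror standard U-Net practice; both are exposed
  in `unet_spec()` rather than hard-coded.
* **Padding.** Same-padding everywhere (rather than valid-padding with
  cropping) keeps outputs aligned with inputs, which makes tile stitching
  during whole-slide inference exact.
* **Input scaling.** RGB is divided by 255; no per-channel standardization,
  so inference needs no dataset statistics.
* **Implementation.** The network, including backpropagation and Adam, is
  implemented as vectorized linear algebra: convolution is im2col (pure
  index gathers against cached geometry tables) followed by a BLAS matrix
  product, and the convolution *backward* pass is expressed as a
  transposed convolution — one more im2col plus one GEMM — rather than a
  scatter-add, which profiled substantially faster in R. Max-pooling and
  nearest-neighbor upsampling are index gathers with exact adjoints.
  Gradient correctness is enforced by central-difference checks over every
  parameter tensor in the test suite.

## The four training objectives

All four losses operate on a `pixel_batch()`: one row per pixel, one
column per class; pixels labelled 255 (ignore) contribute exactly zero.

**Categorical cross-entropy** (`loss_cross_entropy()`): mean over valid
pixels of `-log p_target`. Probabilities are clamped at `1e-12` before the
logarithm — the loss is unbounded at zero probability and training must
not produce `NaN`.

**Focal loss** (`loss_focal()`): cross-entropy modulated by
`alpha (1 - p_t)^gamma`, down-weighting easy abundant pixels so small
compartments (e.g. erythrocytes) keep gradient share. Defaults
`alpha = 0.25, gamma = 2` follow the loss's original authors and are
exposed in `loss_config()` rather than hard-coded.

**Bi-tempered logistic loss** (`loss_bi_tempered()`): two temperatures
make the loss robust to label noise. `t2 >= 1` replaces softmax by a
heavy-tailed *tempered softmax* `y_i = exp_t2(a_i - lambda(a))`, where the
normalizer `lambda` has no closed form; it is found by **bisection** on the
monotone residual `sum(exp_t2(a - lambda)) - 1` (tolerance `1e-9`, cap 100
iterations, both configurable). Bisection converges unconditionally, which
matters more here than speed. `t1 <= 1` tempers the entropy term and
bounds the loss. Defaults `t1 = 0.8, t2 = 1.2` follow the reference
implementation of the loss's authors. The one-hot zero entries use the
conventional limits (`0 * log_t 0 = 0`, `0^(2-t1) = 0`), leaving the
`y_i^(2-t1)/(2-t1)` term as the only off-target contribution. The analytic
gradient differentiates *through* the normalizer
(`d lambda / d a_k = y_k^t2 / sum_j y_j^t2`).

**Lovász-softmax** (`loss_lovasz_softmax()`): the tightest convex
extension of the per-class Jaccard loss. Per class, pixel errors are
sorted in decreasing order (ties broken by pixel index via a stable radix
sort, for determinism) and weighted by first differences of prefix Jaccard
losses (`lovasz_gradient()`). The loss averages over **all** 14 classes by
default — the definition sums over the full label set — with a
`classes = "present"` variant behind a flag. On hard 0/1 predictions each
per-class term equals `1 - IoU` exactly; the test suite also checks soft
inputs against an independent implementation of the sorted-interpolation
extension.

Dice loss is deliberately not offered as a training objective (it
interacts badly with anchor-based class balancing); Dice is used as an
evaluation metric only.

Per-pixel losses are **averaged** (not summed) over valid pixels so the
learning-rate scale is independent of batch geometry.

## Training protocol

`train_config()` defaults encode the full protocol: 512 px patches at
1 µm/px, mini-batches of 5, Adam from `1e-4`, at most 500 epochs × 300
iterations, learning rate halved after every 20 epochs without validation
improvement, and early stop after 50 non-improving epochs
(`early_stop_due()`). Points that were open:

* The optimizer is described as Adam "with momentum values identical to
  the original U-Net", which is internally inconsistent (the original
  U-Net used SGD momentum 0.99). Adam with the conventional
  `beta1 = 0.9, beta2 = 0.999` is used.
* One monitored quantity — the validation loss — drives both the schedule
  and stopping; a Dice monitor is selectable (`monitor = "dice"`).
* Learning-rate patience resets both on improvement and on a reduction.
* Class balancing is realized as **uniform anchor-class patch sampling**
  (`patch_sampler()`): the anchor class of each patch is drawn uniformly
  from the classes present in the sources, then a patch is centered on a
  random pixel of that class.
* Augmentation (`augment_tile()`) covers flips, rotations (multiples of
  90° by default; free angles would need mask-edge handling), elastic
  deformation (smoothed Gaussian displacement fields; bilinear for the
  image, nearest for the mask), Gaussian blur, random gamma, per-channel
  color jitter, contrast, and a stain perturbation implemented as
  scale/shift of per-pixel stain concentrations in optical-density space
  using fixed H&E stain vectors. Geometric transforms act identically on
  image and mask; photometric ones never touch the mask.

## Whole-slide inference

`rescale_to_inference_spacing()` brings scans (typically 0.24 µm/px) to
the network's 1 µm/px operating point with **area-weighted** resampling
(each output pixel averages exactly the source area it covers — the
correct antialiasing scheme for downscale, and mean-preserving).
`plan_tiles()`/`predict_map()` run tiled inference: each tile is read with
a 64 px context margin (reflect-padded at borders) but writes only its
center region, so same-padding seam artifacts — which decay within the
receptive-field half-width — never reach written pixels, and every pixel
is predicted exactly once. Argmax ties break to the lowest class index for
determinism.

## Evaluation

* `dice_per_class()` computes per-class and mean Dice; reference pixels
  labelled ignore are excluded. Classes absent from both maps are flagged
  absent, and the mean either excludes them (default) or counts them as
  zero — the latter reproduces per-center plotting conventions where a
  missing tissue type scores zero. Both modes exist because zero-filling
  systematically penalizes centers lacking a tissue type.
* `crag_merge_map()`/`glas_merge_map()` collapse the epithelial classes
  for gland-benchmark comparison; `relabel_lumen()` relabels reference
  pixels with mean RGB **strictly above 240** (the near-white gland lumen)
  as background, since the schema segments lumina separately.
  `merged_f1()` reports the pixel-level F1 of the merged foreground
  classes, background excluded; for the three-class merge the unweighted
  mean of benign and malignant epithelium F1 is used (the aggregation was
  an open choice; unweighted mean is the symmetric default).
* `wilcoxon_compare()` is the paired two-sided signed-rank test: exact
  null for ≤ 25 informative pairs without ties, normal approximation with
  tie correction otherwise; all-zero differences degenerate to p = 1.
* `quadratic_weighted_kappa()` scores ordinal slide-level agreement with
  `(i-j)^2` penalties; `one_vs_all_roc()` reports per-class AUC, with
  per-fold mean ± sd when fold identifiers are given.

## Slide-level risk classification

`find_fragments()` splits a slide map into connected tissue fragments
(non-background components; 4-connectivity by default — it never merges
diagonal touches; fragments under 1e4 µm² are discarded as debris — the
threshold is exposed). Per fragment, `extract_features()` produces 18
features: the normalized 14-bin class histogram over tissue pixels and
four tumor-cluster statistics (count, mean/min/max area in µm²) computed
after removing clusters **smaller than 30 µm²**. The filter corrects
spurious tumor specks; it applies to the *cluster features only* — the
label map and the histogram are left untouched, keeping the map auditable
(a hard-removal variant would be a destructive edit of the evidence).
Units are µm² (`pixels × spacing²`) so the threshold is
magnification-independent.

`fit_forest()` trains a 1000-tree probability forest in stratified 5-fold
cross-validation over slides. Feature normalization (zero mean/unit
variance) is learned on the training folds only. Fragments are trained
with their slide's label (weak labels — the per-fragment ground truth does
not exist); held-out slides are labelled by their **worst-graded
fragment** under the risk ordering, and the slide's probabilities are the
worst fragment's. Whether training should be per fragment or per slide was
open; fragment-level training is the choice that makes worst-grade
aggregation coherent at prediction time.

## The synthetic-data generator

`generate_label_geometry()` partitions a canvas into spatially coherent
regions by slicing a smooth random field at class-fraction quantiles, with
at least 1% coverage per requested class; gland classes can carry ring
structures whose interiors are flagged as lumen. `render_texture()` paints
each class with a distinguishable base color plus class-specific texture
(smooth modulation, fiber stripes, speckle) and Gaussian noise; lumen
pixels are rendered near-white (mean RGB > 240) so the lumen-relabeling
rule is exercisable. A minimum pairwise color distance is enforced at
construction, making the segmentation task separable by design.

`generate_cohort()` builds labelled slide cases whose composition encodes
the risk semantics: high-risk slides always carry at least one tumor
cluster ≥ 100 µm²; low-grade slides carry dysplastic regions plus tumor
*only* as sub-30 µm² specks (exercising the cluster filter); hyperplasia —
which is deliberately **not** a segmentation class — is recognizable only
through an elevated gland + lamina-propria histogram with at most a small
dysplasia fraction that overlaps the low-grade range, making that pair the
hardest contrast; "other" is benign stroma-dominated tissue. Default
cohort counts (292/693/36/33) mirror the reference cohort's class
imbalance.

What the generator does **not** emulate: stain variation across
laboratories and scanners, annotation noise, tissue-boundary ambiguity,
artifacts (folds, bubbles), or the full morphological diversity of real
H&E. Passing tests therefore demonstrate that the machinery — sampling,
losses, gradients, optimization, stitching, features, cross-validation —
is correct and well-calibrated on separable data; they do not certify
performance on real slides.

## Problem sizes and numerical choices

The package's built-in end-to-end check (`segmentation_benchmark()`)
trains a base-8/depth-2 network on 32 px patches from 200 synthetic
64×64 tiles (5 classes) for 20 epochs × 30 iterations at a learning rate
of `1e-3`, and evaluates mean Dice on 20 held-out tiles. These sizes are
the package's chosen study conditions for a laptop-class CPU: the paper-scale
protocol (512 px patches, base 32, 500×300 iterations) is exposed through
the same configuration objects but is not what the automated checks run.
The higher learning rate is deliberate: with ~600 optimizer steps instead
of 150 000, the step size scales up accordingly; the protocol default
remains `1e-4`. Under these conditions all four losses reach held-out mean
Dice well above 0.85 (typically 0.94-0.98), and the synthetic 160-slide
cohort yields out-of-fold quadratic weighted kappa ≥ 0.9 and high-risk
AUC ≥ 0.95.

Other numerical choices: probability clamp `1e-12`; batch-norm epsilon
`1e-5` with running-statistics momentum 0.1 (evaluation uses running
statistics); bisection tolerance `1e-9` (tightened to `1e-12` inside
gradient checks so finite differences are not polluted by the solver);
stable sorts everywhere a tie could make a run non-reproducible; a single
seed fans out to tile generation, initialization, sampling and fold
assignment.

## Known limitations

* The pure-R network is CPU-bound and meant for method study and testing,
  not for training on real whole-slide cohorts.
* Likelihood maps are quantized to 8 bits per channel when persisted
  (argmax is computed before quantization).
* Stain augmentation is a parametric perturbation, not a learned
  normalization; vendor-specific WSI formats are out of scope (plain and
  tiled PNG/TIFF only).
* Hyperplasia is only a slide-level construct; a dedicated segmentation
  class would require real annotated material.
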