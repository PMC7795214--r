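---
title: "Feature fusion for histopathology patches: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature fusion for histopathology patches: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Grading cervical biopsy tissue into normal, LSIL, HSIL and cancer from
whole-slide images is hard because adjacent grades look similar and the
reading volume is large. `afse` implements a patch-level classification
pipeline for this setting: small RGB tiles cropped from large source images
are described by deep convolutional features and by handcrafted texture
features, the features are scored and pruned by a one-way ANOVA F statistic,
reduced by Laplacian-eigenmap spectral embedding, serially fused, and
classified by a fully connected softmax subnet. Every stage is testable
offline on seeded synthetic data.

## Patch augmentation

Large source images are turned into a patch dataset by SAD-gated random
cropping plus one translated, rotated, zoomed and brightness-shifted variant
per accepted crop, all normalized to `[0, 1]` (division by 255). The sum of
absolute differences `D = sum |S - T|` between the grayscale crop `S` and a
template `T` rejects crops without nuclei: a crop is kept when `D < D_T`.

Decisions the published procedure leaves open, and the choices made here:

* **Template and threshold.** The template construction is not specified; we
  take the pixel-wise mean grayscale of a user-labelled set of
  nucleus-containing crops (`make_crop_gate()`), and estimate `D_T` as the
  maximum SAD between that template and the labelled good crops, times a
  small margin (`estimate_sad_threshold()`). `D_T` remains a plain config
  parameter for users who prefer to tune it by hand.
* **Translation range.** Taken literally, offsets up to the full patch side
  would move all content out of frame, so offsets are drawn from
  `[0, max_translate_frac * side]` with a default fraction of 0.2.
* **Zoom.** Strides are drawn from `{1, 2}` by default (a literal
  `rand(side)` stride would discard nearly the whole patch), and the
  subsampled patch is restored to the working size by bilinear interpolation
  so all downstream descriptors keep a fixed dimension.
* **Borders.** Translation and rotation fill vacated pixels by reflection,
  which preserves local tissue statistics better than zero fill.
* **Reproducibility.** One run seed; each source image consumes an
  independent substream derived from the seed and the image counter, so
  datasets are byte-identical across runs and insensitive to image order.
* **Crop bounds.** The published index bounds allow windows that overrun the
  image edge when the grid index and the random offset are both large; we
  clamp offsets so every window fits.

## Handcrafted texture features (TIF)

The TIF vector is the serial concatenation of an LBP histogram (256 values)
and a HOG descriptor (1152 values), total 1408.

* **LBP** codes compare each interior pixel with its circular neighborhood:
  `code = sum_i p(g_i - g_o) 2^i` with `p(x) = 1` for `x <= 0` — ties map to
  1, exactly as printed, although much of the LBP literature uses the
  opposite convention on `g_i - g_o`. For radius 1 with 8 neighbors the
  8-connected integer ring is used (matching the square-grid illustration of
  the method); bilinear interpolation on the circle is used for larger
  radii. Border pixels are excluded from the histogram, which is normalized
  to a probability vector.
* **HOG** is only constrained by the stated 10 × 10 cell size and the
  1152-length total. The reconstruction used here — resize to 120 × 120,
  10 × 10 cells (12 × 12 grid), 8 unsigned orientation bins on `[0, 180)`
  with magnitude-weighted hard assignment, per-cell L2 normalization, no
  overlapping blocks — is the minimal standard configuration with
  `12 * 12 * 8 = 1152` values, and every element of it is overridable.

## Backbone features

Deep features are the global average pool of the final convolutional block
of a named architecture: ResNet50 v2 (2048), DenseNet121 (1024), Inception
v3 (2048), Inception-ResNet (1536) or VGG19 (512). The builders assemble
these families with 'same' padding throughout, so the pooled dimension — a
pure function of the architecture — matches the published table for any
input size large enough to survive the stride-32 reduction.

The package ships its own lightweight CPU engine (im2col + GEMM convolution,
batch norm, dropout, SGD) rather than binding a deep-learning framework;
forward passes of all five architectures run in seconds on one core, and
backpropagation covers the sequential layer set used by the trainable tiny
backbone and the subnet. Weights initialize He-normal from a seed; a local
weights file can be plugged in when a pre-trained extractor is wanted, and
nothing is ever downloaded.

Fine-tuning follows the published recipe: categorical cross-entropy, SGD
with the piecewise learning-rate staircase (0.1 / 0.01 / 0.001 / 0.0001
switching after epochs 60, 120 and 180), L1 (lasso) regularization of
convolution kernels, dropout, and batch norm in the classification head.
Unstated values default to dropout 0.5, L1 coefficient `1e-4`, batch size
32. The statement that only the first convolutional layer's pre-trained
weights were used is ambiguous (it conflicts with the same paper's
freeze-the-lowest-layers description), so the frozen-layer policy is
explicit config: `"none"`, `"first_conv"` (freeze the first convolution,
train the rest) or `"trunk"` (freeze all convolutions, train the head only —
the only option for the large composite architectures, whose trunks are
forward-only here).

## ANOVA-F selection and spectral embedding

For every feature the one-way ANOVA F statistic is the ratio of between- to
within-class variance:

```
S_A = sum_i n_i (mean_i - grand_mean)^2
S_E = sum_i sum_{x in class i} (x - mean_i)^2
F   = (S_A / df1) / (S_E / df2)
```

Two printed details do not survive contact with the definitions and are
treated as typography: the leading minus signs on the sums of squares
(squared sums are non-negative), and degrees of freedom quoted as
`(s - 1, n - 1)` with `s` the feature length, which is dimensionally wrong
for a per-feature statistic. The default uses the textbook `(k - 1, n - k)`
for `k` classes; a `df = "literal"` mode applies the printed divisors. Since
the divisors are feature-independent constants, both modes produce identical
rankings and identical normalized weights, so selection behavior is
unaffected.

Selection normalizes the F values to weights summing to one, sorts them in
descending order (ties broken by original index for determinism), and keeps
features up to and including the first at which the running sum exceeds
99.9% — a strict "greater than", as printed. Features with zero within-class
variance but positive class signal receive an infinite statistic, are
flagged, rank first, and are excluded from the weight normalization.

The retained features are embedded by Laplacian eigenmaps. The affinity
construction is unstated in the source; we use a binary k-nearest-neighbor
graph (default `k = 10`), with distance ties at the k-th neighbor all
included so duplicated samples receive identical rows, symmetrized by
element-wise max. From the normalized Laplacian
`L = D^(-1/2)(D - A)D^(-1/2)` the `d` smallest non-trivial eigenvectors are
taken; the trivial direction `D^(1/2) 1` is deflated (shifted up) before the
eigendecomposition so that disconnected graphs contribute component
indicators deterministically instead of an arbitrary basis of a degenerate
null space. Rows are rescaled by `D^(-1/2)`, i.e. the coordinates solve the
random-walk eigenproblem; component indicators are then piecewise constant.
A dense symmetric eigensolver is used — desk-scale sample counts make
shift-invert sparse machinery unnecessary.

Spectral embedding is transductive, and how test patches were embedded is
unstated, so both standard resolutions are provided: the default Nystrom
extension maps a new point through the stored training eigenbasis with
weights `1 / (1 - lambda)`, and a `"transductive"` mode embeds train and
test jointly.

Each fused source is reduced to 200 dimensions by default; this per-source
dimension is inferred from the published fused lengths (two sources → 400,
three → 600, four → 800), which are additive and therefore support
per-source reduction rather than reduction of the concatenation. Serial
fusion is column-wise concatenation in the order of the combination code
(C5 = ResNet50 v2 ∪ DenseNet121, …, C14 = all four).

## The fusion subnet

The classifier on fused features is FC(4096) – BN – FC(4096) – BN –
softmax(4) with ReLU activations, in exactly that layer order. Dropout is
placed after each batch norm (the layer table lists none, but the training
recipe adds dropout after the full connection); the default rate is 0.5.
The published L1 entry on the *input* layer has no standard meaning, so L1
is applied to the first FC kernel only. Batch size defaults to 128; weights
are He-normal; there is no early stopping — the schedule runs its fixed
epochs. Training holds out a validation fraction (default 10%, matching the
90/10 global split) for reporting.

## Feature diagnostics and evaluation

Feature quality is compared through chi-square scores (class-conditional
feature sums against their independence expectation), the ANOVA-F weights,
and extremely-randomized-trees importances (ranger with the `extratrees`
split rule, impurity importance, no bootstrap). Each score vector is
normalized to sum to one and sorted descending for plotting. "Sparsity" is
never defined in the source; here it is the fraction of features whose
normalized weight falls below `1e-6` (configurable). Deep features are
min-max scaled to `[0, 1]` before the chi-square test, which requires
non-negative inputs. The Gini coefficient of a weight curve summarizes how
evenly the mass is spread.

Multiclass ROC uses the micro method: the `m x C` 0/1 label matrix and
probability matrix are flattened into one binary problem, a threshold sweep
over the distinct flattened scores produces (FPR, TPR) pairs — tied scores
collapse to one operating point — and the AUC is the trapezoidal integral.
This equals the Mann–Whitney statistic on the flattened vectors, which the
tests verify exactly.

## The synthetic fixture generator

The generator emulates the *structure* of the original dataset, not its
appearance: dark elliptical "nuclei" on a brighter textured stroma, with
nucleus density and size increasing strictly along the severity gradient
(per-class means 8/14/22/34 nuclei and 2.6/3.1/3.7/4.4 px radius at
96 × 96, rescaled with patch area), the published class imbalance
(50,370 : 11,914 : 16,677 : 21,059) scaled down, and per-image nuisance
variation — background brightness, coarse texture amplitude and pixel noise
drawn independently of class — standing in for staining and illumination
variability. Channels get a fixed stain-like weighting. Every image draws
from a substream derived from the dataset seed, so datasets are
byte-identical across runs.

What it does not emulate: real nuclear morphology and chromatin texture,
epithelial architecture, stain chemistry, scanner artifacts. Passing tests
on these fixtures therefore demonstrate that the *pipeline mechanics* —
gating, descriptors, selection, embedding, fusion, training, evaluation —
behave as specified, not that any accuracy level transfers to real tissue.

## Desk-scale experiments

The original headline accuracies were computed on a private hospital dataset
of 100,020 patches at 200 × 200 and are not reproducible without it. Two
orderings are reproduced directionally on the synthetic fixtures:

* `fusion_gain_experiment()` — for each of five seeds, two architecturally
  distinct tiny backbones (3 × 3 vs 5 × 5 kernels, different widths — the
  desk-scale analog of fusing two backbone families) are applied to a
  600-patch, 48 × 48 dataset; each source alone and their serial fusion go
  through the identical selection/embedding/subnet route, and test accuracy
  (25% held out) is compared. The fused representation should match or beat
  the better single source in most seeds (a sign test), mirroring the small
  but consistent published fusion gain.
* `deep_vs_tif_experiment()` — per seed, a tiny backbone is fine-tuned on
  the training split and its pooled features are compared against the TIF
  vector of the same patches under the identical downstream route. Learned
  convolutional features should win, mirroring the published deep-vs-TIF
  ordering. The per-image nuisance variation in the generator is what makes
  this non-trivial: global texture statistics (which LBP histograms capture)
  are confounded by design, while a trained network can localize the class
  signal.

Because single subnet training runs are noisy at this scale relative to a
~1% effect, each configuration's test probabilities are averaged over three
independently seeded subnet trainings before accuracy is measured; the
comparison then reflects the representation rather than one optimization
path. Problem sizes (600/360 patches, 48 px, 16 embedding dimensions per
source, 64-unit hidden layers, 40 epochs at a flat 0.05 learning rate) were
chosen once as the smallest configuration at which the class structure of
the generator is reliably learnable on a single CPU core.

`scripts/acceptance.R` re-runs all of the above from scratch — descriptor
lengths, the five backbone dimensions, fused widths for C5 and C14, the
learning-rate staircase, both directional experiments, and a micro-AUC of a
full fused run — and writes the numbers as JSON.

## Known limitations

* The large backbones are forward-only feature extractors here; full
  backpropagation through their branch/residual composites is not
  implemented (the `"trunk"` policy trains the head instead).
* Spectral embedding uses dense eigendecomposition, practical to a few
  thousand samples; beyond that a sparse eigensolver would be needed.
* The Nystrom extension assumes test points fall in the span of the
  training neighborhood graph; far-out-of-distribution points embed near
  zero.
* The HOG parameterization is one reconstruction consistent with the
  published length, not a confirmed match of the original extractor.
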