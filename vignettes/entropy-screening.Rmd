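---
title: "Entropy-image preprocessing and bichannel CNN screening for referable diabetic retinopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-image preprocessing and bichannel CNN screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(entropyDR)
```

## The screening problem

Diabetic retinopathy (DR) is graded 0 (none) to 4 (proliferative) from colour
fundus photographs. Screening programmes care about one binary decision:
*referable* DR, defined as grade 2 or worse, which warrants referral to a
specialist. entropyDR implements a complete referable-DR detection pipeline
whose central idea is that severity manifests as local *heterogeneity*:
microaneurysms, hemorrhages and exudates are small structures that disturb
otherwise smooth retinal texture. Instead of feeding raw pixels to a
classifier, every photograph is converted into **local Shannon-entropy
images**, per-pixel maps of textural complexity, computed from two
complementary monochrome views of the retina:

* the **luminance** (gray level), `0.299 R + 0.587 G + 0.114 B`, and
* the **green component**, which carries the strongest vessel and lesion
  contrast because retinal pigments reflect green light preferentially.

Both views are first sharpened by **unsharp masking** (UM), and the two
resulting entropy images are consumed jointly by a two-stack ("bichannel")
convolutional network.

## Preprocessing

For a plane $x$ and a Gaussian blur $G_\sigma x$, unsharp masking computes

$$\mathrm{UM}(x) = \mathrm{clip}_{[0,255]}\!\big(\mathrm{round}(x + a\,(x - G_\sigma x))\big),$$

amplifying the high-frequency residual that carries edges and small lesions.
The local entropy at pixel $p$ is the Shannon entropy of the intensity
histogram of the $n \times n$ window centred on $p$:

$$E(p) = -\sum_i P_p(i)\,\log_2 P_p(i), \qquad 0 \log_2 0 \equiv 0,$$

where $P_p(i)$ is the relative frequency of intensity $i$ in the window.
A constant window has entropy 0; a window whose $n^2$ pixels are pairwise
distinct attains the maximum $\log_2 \min(n^2, \mathrm{bins})$ bits. The
entropy image is finally divided by that fixed theoretical maximum so values
lie in $[0, 1]$.

Parameter choices, all exposed as arguments:

| parameter | default | rationale |
|---|---|---|
| window side $n$ | 9 | the block size that maximises detection accuracy for entropy-image screening |
| histogram bins | 256 | one bin per 8-bit level; smaller values model coarser quantisation |
| UM $\sigma$ | 2 px | roughly the lesion scale at the 100×100 working resolution |
| UM amount $a$ | 1 | classic unit-gain high-boost |
| working resolution | 100×100 | small enough for desk-scale training, large enough to retain lesions |

Numerical conventions worth stating exactly:

* **Rounding** is half-up (`floor(x + 0.5)`) wherever a plane returns to the
  8-bit grid (luminance, resize, UM). Entropy needs discrete intensities, so
  luminance is rounded before histogramming.
* **Borders** use symmetric, edge-inclusive reflection for both the Gaussian
  blur and the entropy window, so every output pixel sees a full-size
  neighbourhood and the two stages agree on boundary semantics.
* **Rescaling is global, not per-image.** Dividing by the per-image maximum
  would make entropy values incomparable across images; dividing by the
  fixed bound keeps the unit interval meaningful corpus-wide. An 8-bit
  quantisation between UM and entropy is representable through the `bins`
  argument rather than hard-coded, since it is lossy and unnecessary.
* The **entropy window is sliding**, one output per input pixel, rather than
  disjoint tiles: the network expects full-resolution texture maps.

## Dataset construction

`balance_classes()` brings every grade to a target count, augmenting
under-represented grades with lossless transforms (horizontal/vertical flip,
rotations by multiples of 90°) and subsampling over-represented ones. The
transform cycle guarantees no `(source, transform)` pair repeats before all
pairs are exhausted. `split_train_test()` then assigns train/test splits
stratified by grade. Two orderings are supported:

* **strict (default)** — all records sharing a source image move together,
  so an augmented copy can never sit in the test set while its source is
  trained on. Exact per-stratum counts are met by greedy whole-group
  assignment with swap repair; pathological group-size combinations that
  cannot meet a count exactly raise an error instead of silently leaking.
* **`record_level = TRUE`** — augment first, then sample individual
  records. This reproduces the count arithmetic of screening studies that
  balance before splitting (16,500/1,333/2,000/645/645 source images
  balanced to 33,000 and split 30,000/3,000), at the cost of potential
  near-duplicate leakage, which is why it is not the default.

Rotations are restricted to multiples of 90° by default because they are
pixel-exact; arbitrary angles would introduce interpolation artefacts into
an entropy computation that is deliberately histogram-based.

## The bichannel network

Each input stack applies four blocks of [5×5 convolution (same padding) →
ReLU → 2×2 max-pool], with 32/64/64/128 filters in the reference
configuration; at input side 100 the spatial footprint shrinks
100 → 50 → 25 → 12 → 6. The two stacks are flattened, concatenated, passed
through a ReLU dense layer with dropout, and a single sigmoid unit emits the
referable probability. Training minimises binary cross-entropy with Adam
(reference learning rate 1e-4). A two-way softmax would be mathematically
equivalent; the sigmoid head is simpler.

Design points that were genuinely open and how they were resolved:

* **Dropout placement.** Only the rate (0.3) is dictated by the reference
  architecture. Placing inverted dropout after every pooling stage makes
  evaluation-mode activations systematically differ from training-mode ones
  (the expectation is preserved only through linear maps, and four
  ReLU/pool stages compound the mismatch), which at desk scale produced
  badly calibrated probabilities. Dropout therefore sits after the hidden
  dense layer only, where the following map to the logit is linear and the
  train/eval expectation match is exact. This is also the classical
  placement for convolutional classifiers without batch normalisation.
* **Input standardisation.** Unit-rescaled entropy images concentrate in a
  narrow band (standard deviation ≈ 0.05), far too flat for He-initialised
  filters to see. At the start of training the per-channel mean and standard
  deviation of the training inputs are stored in the model and applied to
  every subsequent forward pass, the ordinary standardisation step of any
  image classifier.
* **Independent stacks.** The two channels use separate, untied weights.
* **Regularisation and schedule.** Decoupled (AdamW-style) weight decay is
  available via `weight_decay` (biases exempt). `lr_decay_factor` applies a
  step learning-rate decay over the final quarter of training — without it
  the endpoint oscillates a full accuracy point between epochs at
  desk-scale sample sizes; `average_tail` optionally averages the
  parameters of the trailing epochs (stochastic weight averaging).
* **Determinism.** One integer seed drives initialisation, shuffling and
  dropout through R's RNG; two builds or two training runs from the same
  seed are bit-identical. Max-pool ties resolve to the first element in
  column-major order.

The convolution and pooling kernels (forward and backward) are compiled
C++; gradients of every parameter tensor are verified against central
finite differences in the test suite.

## Evaluation

`confusion_counts()` calls a score positive when it is `>= threshold`
(ties count positive; default threshold 0.5, configurable because the
operating point behind published sensitivity/specificity pairs is usually
unstated). Accuracy, sensitivity and specificity are reported as
percentages; empty classes raise errors rather than returning `NaN`.
`roc_auc()` sweeps all thresholds, groups tied scores into single diagonal
segments, and integrates trapezoidally — which makes the area identical to
the Mann–Whitney pairwise concordance with ties counted ½ (midrank
convention). The suite checks this identity against an exhaustive
pairwise oracle and against an independent ROC implementation.

## The synthetic fundus phantom

Real screening corpora are large, external downloads. The phantom generator
exists so that every stage — including end-to-end training — is testable
from a seed alone. Each phantom is built from:

* a dark background and a bright circular retina disc with radial falloff
  and mild Gaussian sensor noise (sd 2 intensity levels);
* a brighter optic-disc blob at a random eccentric position;
* 6–10 dark vessels drawn as quadratic Bézier strokes radiating from the
  optic disc, half-width 1–2 px;
* lesions whose **count is Poisson with a strictly increasing per-grade
  mean (0, 2, 6, 12, 20)** — the generative encoding of "severer DR gives
  rise to higher heterogeneity". Bright exudate-like blobs (radius 2–6 px)
  and dark hemorrhage-like blobs (radius 1–4 px) occur with equal
  probability, placed uniformly in the inner disc.
* every vessel/lesion intensity offset is largest in the green plane
  (e.g. vessels darken green by 55 levels vs 18 red / 12 blue), emulating
  the green-contrast property of real fundus photographs.

What the phantom does **not** model: illumination gradients, camera vendor
variation, field-of-view crops, image-quality defects, neovascular fronds,
anatomical variation of the macula. Passing the end-to-end benchmark
therefore demonstrates that the pipeline's machinery works and that its
ordering properties (green ≥ gray, bichannel ≥ single channel) hold on data
with the designed statistical structure — it says nothing quantitative
about large real screening corpora, whose accuracy figures are out of
scope here.

## The desk-scale benchmark

`run_benchmark()` generates a balanced corpus of 2 × 1,000 phantoms at side
100 (non-referable: grades 0/1 evenly; referable: grades 2/3/4 near-evenly),
computes both entropy channels, holds out a grade-stratified 20 % test set,
trains and evaluates. Because 1,600 training images cannot support the
reference 32/64/64/128 architecture, `benchmark_config()` scales the stacks
to 6/12/12/24 filters with a 32-unit dense layer, Adam at 1e-3 with
decoupled weight decay 1e-4 and a 10-fold learning-rate decay over the
final quarter, batch 32, 14 epochs — the same architecture family at a
width the corpus can constrain. The training split is
additionally enlarged with exact horizontal flips (the augmentation
vocabulary of the dataset module; flipping commutes with the entropy
filter, so flipping the entropy image equals preprocessing the flipped
photograph). These problem sizes keep a full run around ten minutes on a
single CPU while leaving the scientific structure of the task intact.

Channel-ablation comparisons (gray-only and green-only stacks against the
bichannel model) are run at a smaller common budget — 4/8/8/16 filters, six
epochs, no augmentation, several seeds — because only the *relative*
ordering is of interest there and each extra configuration multiplies the
compute; the ordering conclusion is taken from seed medians, never from a
single run.

## Known limitations

* The local-entropy filter is O(n²) per pixel; for the window sizes used
  here that is fast, but very large windows would want an incremental
  sliding histogram.
* Strict split mode can fail (with an informative error) when per-stratum
  counts are unreachable by whole source groups; `record_level` or adjusted
  counts are the escape hatches.
* The CNN is CPU-only by design; it is sized for method verification, not
  for production screening throughput.
* Phantom realism is deliberately limited (see above): conclusions about
  real photographs require real photographs.
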