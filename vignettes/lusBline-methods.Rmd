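---
title: "Methods: frame- and clip-level A/B-line classification in lung ultrasound"
author: "lusBline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frame- and clip-level A/B-line classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lung ultrasound (LUS) separates normally aerated lung from
alveolar-interstitial syndrome through two artifact families: *A lines*,
horizontal reverberations of the pleural line repeating at integer
multiples of its depth, and *B lines*, vertical laser-like rays running
from the pleural line to the bottom of the image. The clinical question
is asked of a *clip* (a short video loop at one chest location), but the
natural unit of supervised learning is the *frame*. The two do not line
up: in many pathological clips the B lines come in and out of view with
tidal respiration, so most frames of a B-positive clip can look normal.
`lusBline` implements a two-stage pipeline for this situation:

1. a convolutional classifier maps each masked grayscale frame to a
   probability pair $p = [p_A, p_B]$;
2. a clip-level decision rule turns the ordered sequence
   $P_B = \{p_{B1}, \dots, p_{Bn}\}$ into a single A/B call:
   $$\hat y \;=\; \mathbf 1\!\Bigl[\,\bigvee_{i=1}^{\,n-\tau+1}\;
     \bigwedge_{j=i}^{\,i+\tau-1} \bigl(p_{Bj} \ge t\bigr)\Bigr],$$
   i.e. the clip is B-positive iff some run of $\tau$ consecutive
   frames all reach the classification threshold $t$.

The comparison is inclusive ($p_B \ge t$), so boundary ties count as B
frames; when $n < \tau$ the disjunction is empty and the clip is called
A. With $\tau = 1$ the rule reduces to $\max(P_B) \ge t$. The rule is
monotone: lowering $t$ or $\tau$ can only turn decisions on, which is
what makes the $(t, \tau)$ sweep surfaces (`thresholdSweep()`)
monotone along $\tau$, and is asserted as a property in the test suite.

The baseline it replaces, `classifyClipAveraging()`, thresholds the
mean of $P_B$. On homogeneous clips the two agree, but on a
heterogeneous clip whose B-line episodes cover a minority of frames
the mean is dragged below threshold and the clip is falsely called
normal. The contiguity rule instead asks only for one sufficiently
long episode.

## The frame classifier

The network is the front of a VGG16-style feature hierarchy: three
convolutional blocks of (2, 2, 3) layers with (64, 128, 256)
single-stride $3\times3$ filters and spatial-preserving padding,
2×2 max-pooling after blocks 1 and 2 *only* — the third pool is
dropped so the deepest feature maps stay at 1/4 of the input
resolution — then global average pooling, dropout, and a 2-node dense
softmax head. For the default $128 \times 128$ grayscale input this is
1,734,850 parameters (asserted against the closed-form sum in the
tests). Deeper blocks would add capacity for semantic abstraction that
these low-complexity artifact patterns do not need, while the shallow
truncation keeps single-CPU training tractable.

The backend is a compact single-precision implementation
(im2col + GEMM convolutions, Adam) in Rcpp/RcppArmadillo, single
threaded and deterministic for a fixed seed: weight initialization
(He), shuffling, augmentation draws and dropout masks all derive from
the configured seeds, so two runs with the same seed produce identical
loss histories to float tolerance.

Training choices (`trainConfig()`): Adam with learning rate $10^{-4}$
by default (the end-to-end synthetic runs use $10^{-3}$, which the
near-separable phantom tolerates and which converges in a handful of
epochs), batch size 16, dropout 0.5, early stopping on validation loss
with patience 3 and best-checkpoint restoration, and inverse-frequency
class weighting — A frames outnumber B frames roughly 2:1 in archives
like the one emulated here, and the frame pools inherit that imbalance.
Pretrained initialization is supported only through an explicit weight
list (`buildFrameClassifier(weights =)`); the default is random
initialization so that everything is self-contained and reproducible.

## Beam masking and augmentation

Real ultrasound frames carry vendor screen furniture. `applyMask()`
zeroes everything outside a sector polygon (`BeamMask`); synthetic
frames are born masked, and the operation is idempotent. Training-time
augmentation (`augmentFrame()`) composes rotation (up to ±45°),
translation (up to ±10% of each dimension), magnification (±10%),
one-sided counterclockwise shear (up to 10°), optional horizontal
reflection, and a multiplicative brightness factor in [0.7, 1.3].
The four geometric pieces are composed into a single affine map and
resampled bilinearly once (fill 0), in the fixed order
rotate → shift → zoom → shear, then flip, then brightness, with output
clipped to [0, 1]. Brightness is multiplicative because the useful
invariance for ultrasound is gain, not offset; shear is one-sided
because a symmetric range would double-count the reflection that the
flip already provides. Because a brightness change can lift the
zero background, the training path applies the beam mask *after*
augmentation, and the suite asserts that outside-sector pixels are
exactly zero post-pipeline.

## The synthetic phantom

No public archive of labelled LUS clips exists at the granularity this
pipeline needs (per-frame labels, severity, heterogeneity, patient
grouping), so the package ships a generative phantom
(`generateFrame()`, `generateClip()`, `generateCohort()`) that renders
the features the classifier actually uses, in a fan-shaped sector with
multiplicative speckle:

* a bright pleural arc at a configurable depth fraction (default 0.25);
* A frames: `nALines` horizontal reverberation arcs at integer
  multiples of the pleural depth with geometrically decaying intensity;
* B frames: `bLineCount` vertical rays from the pleural arc to the far
  field, with angular positions drawn per clip and an opacity channel.

Severity follows the clinical taxonomy: fewer than 3 rays is *mild*;
otherwise the fraction of the pleural arc covered by rays decides
*moderate* (< 50%) versus *severe* (> 50%). The generator inverts this
map when a severity grade is requested and the tests re-derive the
grade from the generated geometry.

Heterogeneous B clips model tidal respiration as a sinusoidal phase
(1.2–2.8 cycles per clip): rays fade in and out, and a frame is
labelled B while the phase is above a visibility threshold of 0.7.
This yields contiguous B-frame runs (at least 3 frames long) covering
a *minority* of the clip — matching the clinical picture in which most
frames of a heterogeneous clip show A lines — which is exactly the
regime where clip averaging fails and the contiguity rule is needed.
Defaults for cohort structure follow the archive shape the package
emulates: 38% of patients are B patients, 2–4 clips per patient,
44% of B clips heterogeneous, 30–60 frames per clip, and 60% of
homogeneous clips marked as labelled before the frame-training cutoff.

What the phantom deliberately does *not* model: physically accurate
acoustic propagation, curved-linear or linear probe geometries, vendor
screen furniture, pleural line irregularity, or subpleural
consolidation. Frames are separable by a simple hand-written
ray-energy oracle with ≥ 99% accuracy — by design, since the phantom's
job is to carry a learnable signal through the pipeline. Passing the
end-to-end tests therefore demonstrates that the machinery (pools,
splits, training, inference, sweep) is correct, *not* that the
classifier would reach any particular performance on clinical data.

## Splits and leakage control

`makeFolds()` partitions *patients*, never clips: each patient lands in
exactly one fold, fold assignment is stratified by the patient's
majority class (so both classes appear in every test fold even at small
n — the plan's validity method enforces the partition), and within each
fold a stratified 10% of non-test patients forms the validation set.
`routePools()` keeps the frame-training data and the clip-inference
data disjoint by clip id: only homogeneous clips labelled before a
batch cutoff may train the frame classifier; heterogeneous clips and
late-labelled homogeneous clips form the clip-inference pool. In the
experiment driver, clip-level predictions for a clip always come from
the fold in which its patient is a *test* patient.

## Metrics

`rocAuc()` computes AUC as the tie-aware normalized Mann–Whitney
statistic (ties contribute 1/2), which the tests pin against
brute-force pair counting to $10^{-12}$ and against an independent ROC
implementation. Sensitivity is the true-positive rate on B clips,
specificity the true-negative rate on A clips; per-fold reports
aggregate as mean and sample (n−1) SD. Frame-level ROC pools all test
frames within a fold and averages AUC across folds.

## Explainability

`gradCAM()` targets the last convolution of block 3 — the deepest
spatial maps. With a GAP-plus-dense head the gradient of a class logit
with respect to feature map $k$ is constant, $W_{kc}/(HW)$, so the
channel weights have a closed form and the map is the rectified
weighted sum of the feature maps, bilinearly upsampled and
max-normalized. Overlays default to the blue-is-important colour
convention for parity with common clinical figures; the conventional
jet ordering is available via `convention = "standard"`. On phantom B
frames the generated ray geometry is known (`rayPixelMask()`), so the
suite can test localization quantitatively: mean importance on ray
pixels exceeds off-ray importance on correctly classified frames (sign
test).

## Desk-scale problem sizes

The heavy end-to-end checks run a deliberately compact study: a
40-patient cohort (~120 clips of 24–36 frames at $128\times128$), two
patient-grouped folds, 6 training epochs on a class-balanced sample of
~3 frames per homogeneous training clip, and a sweep over
$t \in \{0.5, \dots, 0.9\}$, $\tau \in 1..12$ (clip lengths bound the
useful $\tau$ range; the full $\tau \le 40$ grid is exercised on
generated 60-frame probability cohorts). These sizes are the package's
choice of a desk-scale experiment: large enough that both folds see
both classes in every pool, small enough to run on one CPU. The
balanced frame sampling oversamples the minority class clip-wise;
without it, small frame pools can be so imbalanced that early epochs
collapse to the majority class.

## Numerical notes and edge cases

* Empty probability sequences, empty clips, single-class training
  pools, single-class sweep sets, mismatched mask sizes and invalid
  labels are rejected with diagnostics rather than silently handled.
* `classifyClip` reports the *earliest* triggering window; operating
  point ties break toward smaller $\tau$, then smaller $t$ — the less
  aggressive setting.
* Dropout is disabled at inference; gradients for Grad-CAM use the
  deterministic inference path.
* Weights live in the S4 object as portable R arrays; the live backend
  is cached in an environment and rebuilt after deserialization, so a
  saved model predicts identically when reloaded.
* PNG round trips quantize to 8 bits; tests use a 1/255 tolerance.

## Known limitations

The phantom's separability makes near-ceiling accuracy the *correctness
bar*, not a performance claim; clinical deployment would face probe and
preset variability, operator dependence and pathology classes that the
generator does not emulate. The averaging baseline is a plain
mean-threshold rule; richer pooling (e.g. learned aggregation or
temporal models) is deliberately out of scope, as the clip rule's point
is to stay interpretable in terms of two clinically meaningful
thresholds.
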