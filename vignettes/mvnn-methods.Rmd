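---
title: "Methods: the multi-view multi-scale attention model and its verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-view multi-scale attention model and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and design

`mvnn` is a CPU-native reference implementation of a two-view mammogram
classifier: a multi-scale attention DenseNet backbone per view (CC and MLO),
a 1024-unit fusion layer, and a two-stage cascade (normal/abnormal, then
benign/malignant). Every layer, including backpropagation, is implemented in
R with RcppArmadillo kernels (im2col + GEMM convolutions), because the model
itself — the attention module, the multi-scale dense block, the fusion
training protocol — is the subject of the package, and a from-scratch
implementation keeps every computation inspectable and testable against
independent oracles.

## The model

### CSAM: parallel channel and spatial attention

For a feature map $F \in \mathbb{R}^{C \times H \times W}$ the module forms

$$M_C(F) = \sigma\big(\mathrm{MLP}(\mathrm{AvgPool}(F)) +
\mathrm{MLP}(\mathrm{MaxPool}(F))\big), \qquad
M_S(F) = \sigma\big(f([\mathrm{AvgPool}(F);\mathrm{MaxPool}(F)])\big),$$

and aggregates both branches with residual connections,
$F' = (F + F \otimes M_C) + (F + F \otimes M_S)$. Design points that the
printed formulas leave open, and how this implementation resolves them:

* The channel MLP is shared between the average and max descriptors and the
  two MLP outputs are summed **before** the sigmoid. (The alternative
  reading, pooling-sum before a single MLP pass, would make weight sharing
  meaningless; sharing is only observable under MLP-then-sum.)
* The MLP hidden activation is ReLU; hidden width is $C/r$ with $r = 16$ by
  default (configurable; $r$ must divide $C$).
* The spatial chain is 1×1 (2→1 channels) → 7×1 → 1×7, all same-padded, with
  no nonlinearity between the convolutions and a single sigmoid at the end.
* Biases exist and start at zero; weights use seeded Kaiming-style
  initialization. No normalization layer exists inside the module.

Two consequences are used as analytic test oracles: with all parameters
zero, both maps are uniformly $\sigma(0) = 0.5$ and $F' = 3F$ exactly; and
in general $F' = 2F + F \otimes (M_C \oplus M_S)$ with $\oplus$ the
broadcast sum.

### Multi-scale dense blocks

The building block projects its input with BN–ReLU–1×1 to $k$ channels
($k = 32$ by default, necessarily divisible by 4), splits it contiguously
into $X_1 \dots X_4$ of $g = k/4$ channels, and applies the hierarchical
residual recursion $y_1 = X_1$, $y_i = K_i(X_i + y_{i-1})$, where each
$K_i$ is BN–ReLU–3×1 conv–BN–ReLU–1×3 conv (same padding). The factorized
pair costs $6g^2$ weights against $9g^2$ for a full 3×3. CSAM is applied
once, to the concatenation $[y_1; y_2; y_3; y_4]$, and the result is the
block's $k$ new channels; the dense block concatenates them onto its input,
so layer $l$ computes $x_l = H_l([x_0, \dots, x_{l-1}])$. With identity impulse kernels and
normalization disabled, the recursion collapses to cumulative subset sums —
the block's exactness oracle — and impulse-response support widths of 3
(one K) versus 7 (three K) demonstrate the receptive-field growth.

The canonical backbone (depth 186 under the convention 1 stem + 2 per block
+ 1 per transition + 1 classifier) uses a 7×7 stride-2 stem into 64
channels, a 3×3 stride-2 max pool, dense blocks of (6, 12, 24, 32, 16)
building blocks interleaved with four transitions (BN → 1×1 conv halving
channels → 2×2 average pool; no ReLU, following the printed composition),
and an 8×8 global average pool. A final normalization + ReLU precedes the
pool, the standard closing of pre-activation dense networks. The per-stage
output sizes on a 512×512 input are 256, 128 (stem), 128/128→64, 64/64→32,
32/32→16, 16/16→8, 8, 1 — asserted by a real forward pass, not by
arithmetic alone. The stem width (64) and growth rate (32) are conventional
defaults; both are configurable, which is how the desk-scale variants used
in tests (48 px input, blocks (2,2), k = 8, r = 4) are built.

### Normalization at batch size one

This implementation processes one image at a time and therefore computes
normalization statistics per sample and per channel, identically at train
and test time (batch normalization evaluated at batch size one, i.e.
instance normalization with learned affine). This avoids the train/test
statistics mismatch that running moments would create at these batch sizes
and makes every forward pass a pure function of its input and weights —
useful for the freeze audit, which can compare weight vectors bit-for-bit.
The cost is that per-image global intensity shifts are largely removed as a
cue, which makes the phantom tasks harder than their pixel statistics
suggest. Mini-batches exist at the optimizer level: gradients are averaged
over the configured batch before each SGD step.

### Fusion and the two-phase protocol

The two branches are architecturally identical but never share weights.
Their pooled feature vectors are concatenated, passed through a 1024-unit
affine + ReLU fusion layer and a 2-way softmax head. Training follows the
two-phase protocol: (1) each branch plus a private head is trained on its
own view (SGD: momentum 0.9, lr 0.001, weight decay 1e-4, batch 16, 300
epochs as canonical defaults — all overridable, and desk-scale runs use
larger learning rates and far fewer epochs); (2) the fusion layer and head
are fine-tuned on view pairs while both branches stay frozen. Freezing is
structural — branch features are computed once and the optimizer never sees
branch parameters — and is audited bit-for-bit in the tests. The loss is
cross-entropy on the softmax; the learning-rate schedule is constant by
default. The cascade applies the screening model at threshold 0.5
(configurable) and routes abnormal cases to the independently trained
diagnosis model.

## Evaluation

Accuracy and sensitivity are computed at the decision threshold; the ROC is
swept over the distinct observed scores and the AUC is the trapezoidal area,
which equals the Mann–Whitney pairwise-ordering probability with ties
counted half — the test suite asserts this equivalence on random instances
and cross-checks against the pROC package. Fold plans are stratified within
class (each fold within one case of proportional), and cross-validated
metrics are reported as means over folds with per-fold values retained.
A single-class label vector makes the AUC undefined and it is reported as
`NA` with a warning, never silently as 0. Per-lesion-type accuracy splits
the abnormal cases into mass and calcification subsets.

## Saliency

Heat maps are gradient-weighted class activation maps at the feature map
entering the global average pool: because the pool is a global mean, the
gradient of a class logit with respect to that activation is spatially
constant per channel and follows in closed form through the fusion ReLU and
head weights. The rectified weighted channel sum is min–max normalized
(a constant map maps to all zeros; normalization is idempotent), upsampled
bilinearly to the view size, and blended with a jet colormap (alpha 0.4).
The reported P is the softmax score of the target class. Two caveats are
deliberate: the activation is branch-local, but the channel weights pass
through the shared fusion layer, so the map is not strictly independent of
the other view; and the outermost cells of the coarse activation map carry
zero-padding artifacts (amplified by per-sample normalization), so the
localization test evaluates the peak over the map interior. Which layer to
visualize is in principle a free choice; this implementation taps the last
dense block's output as the most class-discriminative map.

## The phantom generator

Phantoms emulate just enough structure for every pipeline stage to be
exercised: a half-elliptical bright breast region against dark background,
smoothed-noise parenchymal texture, a pectoral wedge only in the MLO view,
and — for abnormal cases — a planted lesion. Masses are Gaussian blobs
(smooth if benign; with radial spicules if malignant); calcifications are
clusters of n (default 6) 1–3 px bright specks placed on jittered rings so
the cluster always yields exactly n connected components. Cross-view
consistency is modeled as a shared normalized depth coordinate only; there
is no physical projection geometry, no breast-density model, and no
radiographic noise model. Consequently, passing phantom tests establishes
that the architecture, optimizer, metrics and saliency machinery work and
that the generator emits learnable signal — it says nothing about clinical
performance on real mammograms.

Default generator parameters (contrast 0.35 over local background, mass
radius 5–9% of the image side) produce visible but non-trivial lesions. The
separability sanity check ("a small model reaches > 0.9 held-out screening
accuracy") uses the exposed difficulty knobs — mass-only lesions, contrast
0.8, radius 18–28% — because at desk scale (tens of cases, a two-block
backbone, minutes of CPU) subtler lesions lead to memorization without
generalization; the knobs exist precisely so tests can set task difficulty.

## Problem sizes and numerical choices

Tests and the acceptance script run the canonical 186-layer network only in
forward mode (one 512×512 pass, a few seconds) and train reduced variants:
48 px inputs, blocks (2,2), growth 8, reduction 4, hidden width 16–64,
datasets of 8–60 phantom cases. These sizes were chosen so the whole suite
verifies training end-to-end in minutes on one CPU while leaving the
canonical configuration assertable. Other numerical choices: normalization
epsilon 1e-5; min–max guards treat ranges below 1e-12 as degenerate (maps
to zero); max-pool argmax ties break toward the first index in column-major
order; softmax is computed with max subtraction; cross-entropy clamps
probabilities at 1e-12. Augmentation samples 1–2 geometric then 1–2
photometric operations per output, uniformly — the minimal reading of
"randomly combining" two stages — with crop fraction 0.85–1, gamma 0.8–1.2,
noise sigma 0.01, and the canonical scale range [0.8, 1] and ±10%
translations; all draws derive from one seed, and outputs are clipped to
[0, 1]. The two-view expansion emits the closure {identity, CC flip,
joint horizontal flip, composition}, reducible to the two explicit rules.

## Known limitations

* No GPU path and no minibatch-level normalization statistics; wall-clock
  limits keep phantom experiments at tens of cases, so reported phantom
  metrics carry wide confidence intervals.
* Dropout is absent (never specified); overfitting control is limited to
  weight decay and augmentation.
* The checkpoint format is R-native serialization (with an embedded JSON
  manifest); it is not interoperable with other frameworks.
* The phantom generator's correlation model (shared depth coordinate) is far
  weaker than real CC/MLO projection geometry; fusion gains measured on
  phantoms underestimate or misestimate those on clinical data.
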