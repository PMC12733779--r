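---
title: "mambaseg: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mambaseg: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(mambaseg)
```

This vignette is the package's account of the science it implements: the
network and its assumptions, every tunable that matters, the numerical
conventions, and the design decisions taken where the architecture left
choices open. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The segmentation model

The network is a five-stage U-shaped encoder–decoder for binary lesion
segmentation of RGB dermoscopy images. For a 256×256 input, stage *i* of the
encoder carries `C_i = 8 i` channels at resolution `256 / 2^(i-1)`:
(8, 256²), (16, 128²), (24, 64²), (32, 32²), (40, 16²). Stage 1 keeps full
resolution (stride 1), stages 2–5 halve it. The network is fully
convolutional, so any input with sides divisible by 16 is accepted; the
printed schedule refers to 256.

### 1.1 Selective-scan (SS2D) blocks

Global context is mixed by two-dimensional selective-scan state-space
blocks. A feature map is flattened along four directional paths — rows
left→right, rows right→left, columns top→bottom, columns bottom→top; each
direction is a bijection between grid positions and sequence indices, so the
expansion loses nothing and the merge can invert it exactly (`scan_perms()`,
`cross_scan()`, `scan_merge()`; the bijection is tested exhaustively up to
8×8 grids).

Each path runs the S6 recurrence per channel with hidden state size `d`
(`d_state`):

\[
h_t = e^{\Delta_t A} h_{t-1} + \frac{e^{\Delta_t A} - 1}{A} B_t x_t,
\qquad y_t = C_t h_t + D x_t,
\]

with `h_0 = 0`. The step size `Δ_t = softplus(W_Δ ξ_t + b_Δ) > 0` and the
projections `B_t, C_t` are linear functions of the token (through a shared
`E → (r + 2d)` projection of rank `r = dt_rank`), which makes the scan
*selective*: the state decay and input gain depend on content. `A` is stored
as `−exp(A_log)` so it stays strictly negative and the discrete decay
`exp(Δ_t A)` lies in (0, 1); with bounded input the hidden state is bounded
(tested over 10⁴ tokens). We use the exact zero-order-hold discretization of
the input term, `(e^{\Delta A}-1)/A \cdot B`, rather than the first-order
shortcut `ΔB`; the closed-form impulse response
`y_t = (1-e^{-1}) e^{-(t-1)}` for `A=−1, Δ=1, B=C=1, D=0` is frozen in a
test. As `Δ → 0` the decay tends to the identity and the input gain to zero,
so `y → D x`.

A block computes `v1 · SS2D(LN(x)) + v2 · x`, where SS2D is: channel layer
norm → pointwise in-projection `C → E` (`E = round(expand · C)`) → SiLU →
four-direction scan → merge (sum of the four inverse placements) → layer
norm → pointwise out-projection `E → C`. `v1 = 0, v2 = 1` is the exact
identity, which is how the Mamba-ablation switches are implemented.

Initialization follows standard S6 practice: `A_log[e, j] = log j`
(state-frequency spread), `D = 1`, `softplus(b_Δ)` log-uniform on
`[10⁻³, 10⁻¹]`, all projections Kaiming-uniform.

### 1.2 Prompt encoder stages

Each encoder stage first runs an inverted-pyramid convolution: a large-kernel
(7×7) depthwise convolution with the stage stride, a pointwise expansion to
the stage width, a small (3×3) depthwise convolution, and a pointwise
aggregation — coarse receptive field first, detail second, depthwise
separable throughout to stay lightweight. A vision-Mamba block on `f_ipc`
gives the global path `f_m`, and the two are fused by

\[ f_{et} = \mathrm{Conv}_{1\times1}(\lambda_1 f_m + \lambda_2 f_{ipc}), \qquad
\lambda_1 = \lambda_2 = 0.5 . \]

Two *self-prompt masks* are distilled by learned channels→one projections:
`p1 = sigmoid(BN(Σ_i ω_i f_ipc^i))` from the convolutional path (detail cue)
and `p2 = sigmoid(LN(Σ_i ω_i f_m^i))` from the Mamba path (saliency cue);
both are single-channel maps strictly inside (0, 1) and are added onto the
fused features with weights 1, broadcast across channels:
`f_pt = f_et + p1 + p2`. The prompts propagate forward implicitly, through
`f_pt` being the next stage's input; no explicit cross-stage mask passing
exists. The ω are ordinary trainable 1×1 weights, not hyperparameters.

Open choice resolved: the Mamba path consumes `f_ipc` (not the raw stage
input), because the fusion composes both operands at the post-pyramid
geometry; the residual inside the block then requires shape agreement, so
all stage-internal maps carry the stage's output width.

### 1.3 Attention-gated decoder stages

A decoder stage applies a vision-Mamba pre-pass `f_vmt`, four parallel
depthwise-separable branches with kernels 3/5/7/9 (each pointwise-projected
to C/4 channels and concatenated back to C), and a 3×3 depthwise + pointwise
context embedding with batch norm. Then the EASC gate chain:

* **Edge gate**: `x̄ = BN(x − AvgPool₃(DWConv₇(x)))`, gate =
  `sigmoid(Conv₁ₓ₁(x̄))`, a single-channel map; output `gate ⊙ x + x`. The
  average pool is 3×3, stride 1, zero-padded with divisor 9 (size
  preservation is required by the subtraction).
* **Spatial gate**: `BN(DWConv₇) → BN(DWConv₃) → Conv₁ₓ₁→1`, gate =
  `sigmoid(η(·))`; the kernel schedule 7 → 3 → 1 reads the third step as the
  pointwise score projection, which leaves no dangling layer.
* **Channel gate**: global max pool to 1×1 (a per-channel descriptor is the
  only consistent target size), `ReLU(Conv₁ₓ₁)`, `sigmoid(Conv₁ₓ₁)`, C×1×1
  gate broadcast spatially. Its input is the spatial-gate output (the chain
  runs edge → spatial → channel).

Each gate is multiplicative with an additive residual, so zero input maps to
zero and, for strictly positive input, `x < out < 2x` elementwise (gates are
strictly inside (0, 1)). The stage output adds a skip back onto the Mamba
pre-pass: `f_mt = EASC(...) + f_vmt`. η is ReLU by default (exposed in the
config); disabling any gate replaces it by the identity and removes its
parameters — pure configuration.

### 1.4 Cross-attention skip fusion

For stages t = 1..4, the decoder output of stage t+1 is upsampled ×2
(bilinear) and projected pointwise to the stage width as the query Q; the
encoder output `f_pt` is projected as the key K (both followed by BN and
flattened to C×N). The affinity `Q Kᵀ` is C×C — the only conformable product
for C×N operands — so the cost of the block is linear in N (asserted on the
analytic profile). The row-softmax is normalized by `τ = √N` (the reduced
axis of the dot product has length N). The weight matrix is applied to two
values — V₁ = Q (semantic self-guidance) and V₂ = flattened `f_pt` (texture
detail) — summed, reshaped, and passed through a pointwise conv + η. The
deepest stage has no deeper decoder feature, so stage 5 feeds the encoder
output directly to its decoder stage; disabling fusion passes `f_pt` as a
plain skip.

### 1.5 Heads and loss

Every decoder stage gets an independent head — pointwise `C → h_t`, η,
pointwise `h_t → 1` — bilinearly upsampled to input size. The training
objective is the deeply supervised sum over the five stages

\[ L = \sum_t w_t \left( \lambda_{BCE}\, \mathrm{BCE}(p_t, y) +
\lambda_{Dice}\,\mathrm{Dice}(p_t, y) \right), \]

with `w = (1,1,1,1,1)` and `λ_BCE = λ_Dice = 1` by default (the alternative
schedule `(1, 0.75, 0.5, 0.25, 0.1)` is accepted in the config). The final
probability map is the sigmoid of the stage-1 head, thresholded at 0.5.

## 2. Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `stage_channels` | 8,16,24,32,40 | encoder/decoder widths, `C_i = 8i` |
| `large_kernel`, `small_kernel` | 7, 3 | inverted-pyramid kernels (odd; even rejected by construction) |
| `lambda1`, `lambda2` | 0.5, 0.5 | global/local fusion weights, in (0,1] |
| `prompt_lambda1/2` | 1, 1 | additive prompt weights |
| `branch_kernels` | 3,5,7,9 | decoder multi-scale depthwise kernels (2i+1) |
| `eta` | relu | activation of gates, fusion output and heads |
| `enc_mamba$d_state` | 1,3,8,28,112 | per-stage S6 state size, encoder |
| `dec_mamba$d_state` | 1,2,32,64,160 | per-stage S6 state size, decoder |
| `*_mamba$dt_rank` | 1..5 | step-size projection rank per stage |
| `*_mamba$expand` | 1.5 | inner width multiplier `E = round(1.5 C)` |
| `head_hidden` | 12,12,16,64,72 | per-stage head widths |
| loss `epsilon` | 1 | Laplace smoothing of Dice |
| AdamW | lr 1e-3, β (0.9, 0.999), eps 1e-8, wd 1e-2 | optimizer |
| schedule | cosine, T_max 50, eta_min 1e-5, 200 epochs, batch 8 | training protocol |
| augmentation | flips p = 0.5 each, rotation ±30° | identical on image and mask (nearest-neighbour for masks) |

The S6 internals (state sizes, rank, expansion) and head widths are not
dictated by the architecture description; the only constraint given for them
is the component budget. They were therefore calibrated **once** so the
default model hits the reference budget — 0.383 M parameters and
1.159 GFLOPs in total; encoder 0.135 M / 0.328 G, decoder including fusion
0.242 M / 0.816 G, heads 0.006 M / 0.015 G — and then frozen. The state
sizes grow with depth (tiny states at high resolution, large states where
tokens are few), which is also where the FLOP/parameter trade-off pushes
them: at stage 1 every unit of state size costs 65 536 tokens' worth of
scan work, at stage 5 only 256. Head widths follow the same logic in
reverse: wide heads are affordable only at coarse stages. The analytic
parameter counts are asserted to equal the instantiated model exactly, for
the default and for every ablation switch.

Cosine schedule and epochs: the protocol specifies both 200 epochs and
T_max = 50; the implementation follows the standard cosine-annealing
definition, which continues along the cosine past T_max (so the learning
rate oscillates with period 100 epochs). Both values are plain config
fields.

## 3. FLOP-counting convention

FLOPs are multiply–accumulates (1 MAC = 1 FLOP), the convention of the
common profilers: a convolution costs `k² · C_in/g · C_out · H_out W_out`
(bias excluded), a dense map `r_in r_out` per token, the attention block
`3 C² N` (one affinity, the weights applied to both value branches), and the
selective scan `L (6 E d + 2 E)` per direction — discretization (exponential
and multiply), state update, output projection and skip. Normalizations,
activations, pooling and interpolation are not counted. `count_budget()`
implements this analytically; `scripts/acceptance.R` reports it.

## 4. Numerical choices

* **Dice smoothing**: ε = 1 in numerator and denominator; both masks empty
  gives loss 0. The plain formula is undefined there.
* **BCE**: probabilities clamped to `[10⁻⁷, 1 − 10⁻⁷]`; the training path
  uses the softplus form of BCE-with-logits, which is stable without
  clamping and agrees with the clamped formula to within 10⁻¹⁰ on
  non-degenerate inputs (tested).
* **Prediction threshold**: 0.5 on the stage-1 sigmoid.
* **Batch normalization** runs per image over the spatial grid during
  training (the training loop processes images singly and accumulates
  gradients over the batch) and uses running statistics (momentum 0.1) in
  eval mode. Forward passes in eval mode are exactly deterministic.
* **Scan stability**: `exp(ΔA)` is flushed to exact zero below e⁻⁶⁰, far
  above the subnormal range, so long scans neither underflow gradually nor
  hit denormal slow paths.
* **Metrics with empty classes**: a ratio with zero denominator is 1 when
  the class is absent from both maps and 0 otherwise. mIoU is the foreground
  IoU `TP/(TP+FP+FN)` as printed in the skin-lesion literature (DSC =
  2·mIoU/(1+mIoU) ≥ mIoU always); a two-class mean is available behind a
  flag.
* **HD95**: boundary pixels are foreground pixels with a background
  4-neighbour (the image border counts as background); directed distances
  are nearest-neighbour Euclidean distances between boundary pixel centres;
  the 95th percentile uses R's default (type-7) quantile; the result is the
  maximum of the two directed values. Percentile trimming is adopted —
  that is what the "95" means — even though the bare max would be the full
  Hausdorff distance. One empty mask returns the image diagonal; two empty
  masks return 0. The whole pipeline is tested against an all-pairs brute
  force on random 32×32 masks.
* **Bilinear resizing** uses the half-pixel-centre (align-corners-false)
  convention.
* **Scan order**: `row_fwd` is left-to-right then top-to-bottom, `col_fwd`
  top-to-bottom then left-to-right, backward variants exact reversals. Any
  consistent bijection is equivalent under the merge-inverse property; this
  one is frozen and tested by enumeration.

## 5. The synthetic generator

`generate_pair()` emulates the properties that make dermoscopy segmentation
hard at desk scale: one star-convex lesion `r(θ) = r₀(1 + Σ a_k sin(kθ +
φ_k))` inside a rotated ellipse frame (star-convexity guarantees a single
connected component and yields an exact analytic rasterization oracle at
zero perturbation); a skin-tone background with a smooth illumination
gradient and speckle; a configurable lesion/skin contrast with the boundary
blurred in the image (never in the mask); and optional dark hair-like arcs
that occlude both lesion and skin without touching the mask. Area fraction
is kept inside (0.05, 0.40) by rejection sampling. Masks are written as
single-channel {0, 255} PNG and binarized at >127 on load; a 7:3 train/test
split is recorded in the manifest.

What it does **not** emulate: real pigment-network texture, multi-lesion
scenes, ruler and gel artifacts, color calibration drift, and annotation
noise. Passing the suite therefore demonstrates that the implementation is
faithful and trainable, not that the architecture reaches any particular
accuracy on clinical data; benchmark-level training on ISIC-scale datasets
requires GPU-class resources and is out of scope for this package.

## 6. Problem sizes used by the tests

Oracle and invariant tests run on fixtures of at most 8×8 spatial positions.
Full-schedule checks run two forward passes at 256×256. The learning-sanity
check memorizes 8 synthetic pairs at 32×32 — the smallest size exercising
all five stages — with full-batch AdamW at constant learning rate 2·10⁻³ and
no weight decay (a pure-memorization setting; the cosine schedule and weight
decay belong to real training runs) and requires training DSC ≥ 0.95 within
300 steps, evaluated on the training-mode forward. The whole suite completes
in a few minutes on one CPU.

## 7. Known limitations

* Training is CPU-bound R + Armadillo; it is meant for method study and
  small experiments, not for 200-epoch runs on thousands of images.
* Batch norm statistics come from single-image batches; very small lesions
  at low resolution make the eval-mode running statistics lag behind
  training statistics for the first few epochs.
* The attention fusion uses the channel-affinity (C×C) reading of the
  single-head attention; a spatial-affinity (N×N) reading would be quadratic
  in pixels and contradict the linear-cost property asserted by the
  profiler, but it remains the other defensible interpretation.
* Checkpoints are RDS files of plain arrays; they are portable across
  platforms but not across incompatible config changes (the loader checks
  parameter names).
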