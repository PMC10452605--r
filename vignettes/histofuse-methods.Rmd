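---
title: "histofuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histofuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`histofuse` classifies H&E histology tiles (five classes in the canonical
colon/lung layout: colon adenocarcinoma and benign colon tissue; lung
adenocarcinoma, benign lung tissue and squamous cell carcinoma) by fusing
a handcrafted multi-scale texture descriptor with features learned by a
compact convolutional network. This vignette explains each component's
model and assumptions, the tunable parameters and their defaults, the
numerical choices, what the synthetic generator does and does not emulate,
and the known limitations.

## 1. Stain normalization

Slides from different laboratories differ in stain hue and intensity.
Following the Beer–Lambert law, transmitted intensity in channel
$c \in \{R,G,B\}$ is

$$ I_c = I_0 \cdot 10^{-\sum_{s=1}^{2} C_s \, M_{s,c}}, $$

where $M$ is the $2\times3$ matrix of unit-norm stain vectors
(hematoxylin-like and eosin-like) and $C_s$ are per-pixel concentrations.
Stain contributions are additive in optical density
$\mathrm{OD}_c = -\log_{10}\!\big((I_c+\varepsilon)/(I_0+\varepsilon)\big)$
with $I_0 = 255$, $\varepsilon = 1$. The $\varepsilon$ offset appears in
both numerator and denominator so that $\mathrm{OD}(255) = 0$ exactly and
the transform is non-negative and strictly decreasing — the three
invariants the downstream unmixing relies on.

Estimation (`estimate_stain_profile()`) is Macenko-style:

1. **Background masking** in CIELAB lightness: a pixel is background iff
   $L > 0.9 \cdot 100$ (`l_threshold = 0.9`; glass is near-white). CIELAB
   is used *only* for masking; all stain algebra happens in OD computed
   from RGB, which keeps the physical model coherent. A tile whose every
   pixel is background carries no stain information and is rejected
   (`"no tissue"`).
2. **Stain plane**: SVD of the mean-centred foreground OD cloud; the two
   leading right-singular vectors span the stain plane. For pixels of the
   two-stain model the mean also lies in the stain span, so centring does
   not bias the plane; a cloud of rank < 2 (all pixels on one ray) is
   rejected as `"degenerate stain geometry"`.
3. **Extreme angles**: pixels are projected into the plane and the stain
   vectors taken at the 1% and 99% percentile angles
   (`alpha = 0.01`), which is robust to outliers while still reaching the
   nearly pure-stain pixels. Vectors are unit-normalised with a
   deterministic sign convention (first nonzero component positive) and
   ordered with the larger blue-channel OD (hematoxylin-like) first, so
   repeated estimation is bit-reproducible.
4. **Concentrations** (`compute_concentrations()`): least-squares
   projection of each OD pixel onto the two stain vectors, negatives
   clamped to zero.
5. **Reference matching** (`normalize_to_reference()`): each stain's
   concentrations are rescaled by the ratio of the reference to the source
   99th-percentile concentration (`conc_quantile = 0.99`), then
   reconstructed through the *reference* stain matrix and clipped to
   $[0,255]$.

The classical formulation writes the final rescaling as per-RGB-channel
statistics ratios; whether those statistics are stain vectors or channel
maxima is ambiguous in that notation. We adopt per-*stain* rescaling in
concentration space — the physically meaningful reading — and keep the
per-channel 99th-percentile OD statistics in the profile
(`channel_scales`) for diagnostics and serialization.

Two consequences worth knowing. Self-normalization is a near-identity
*of the two-stain model*: any off-plane component of a pixel (e.g.
sensor noise) is necessarily removed by the rank-2 unmixing, so the
"within 3 intensity levels" property is asserted on noise-free rendered
tiles; with additive noise of standard deviation $\sigma$ the removed
component can reach a few $\sigma$. Second, normalization deliberately
erases inter-laboratory stain differences — classes that differ *only* by
stain become indistinguishable downstream, which is the intended
behaviour of the step.

## 2. The multi-scale binary-pattern descriptor (GLPP)

For a centre pixel $g_c$ and its $P$ neighbours $g_0,\dots,g_{P-1}$ on a
circle of radius $r$ (neighbour 0 due east, clockwise order in image
coordinates, i.e. toward increasing row first), the clockwise code is the
decimal value of the bit string $b_0 b_1 \cdots b_{P-1}$ (most significant
bit first) with $b_k = \mathbf{1}[\,g_k \ge g_c\,]$; the $\ge$ convention
makes a constant patch produce the all-ones code $2^P - 1$. The
counterclockwise pass visits the same neighbours in reverse order
(starting one step counterclockwise of east and ending at east), so its
code is exactly the $P$-bit reversal of the clockwise code — this is the
convention under which the two-pass construction has a closed form, and
it is asserted as a property. The fused code is the larger of the two.
Pixels within $\lceil r \rceil$ of a border are invalid and excluded.

The *pyramid* repeats this over a schedule of growing neighbourhoods,
default $(r, P) \in \{(1,8), (2,16), (3,24)\}$ — local to global — and
concatenates one normalised histogram per scale:

* $P \le 12$: full binning, $2^P$ bins;
* $P > 12$: a $2^P$-bin histogram is infeasible and statistically vacuous
  ($2^{16}$, $2^{24}$ bins for a few thousand pixels), so uniform-pattern
  binning is used: codes whose circular bit string has at most two 0–1
  transitions are binned by their number of ones ($P+1$ bins), all other
  codes share one bin — $P+2$ bins, the standard aggregation for large-$P$
  circular binary patterns.

Each per-scale block is normalised to sum to one, so the default feature
has $2^8 + 18 + 26 = 300$ entries. The descriptor feeds on the CIELAB
lightness of the (stain-normalized) tile, rescaled to $[0,255]$
(`tile_lightness()`); descriptor formulations of this family leave the
grayscale channel unspecified and lightness is the natural photometric
choice.

Numerical choices: non-integer circle positions are sampled with bilinear
interpolation by default (`nearest` available). Comparisons of *raw*
pixels are exactly invariant under strictly increasing intensity maps;
interpolation does not commute with nonlinear maps, so the
monotone-invariance property is exact under `nearest` and approximate
under `bilinear` — the invariance tests use `nearest`. Near-integer
offsets are snapped (tolerance $10^{-9}$) so both interpolators agree on
exact grid points and 90° rotations permute neighbours exactly; in
uniform mode the histogram is invariant under such rotations (ones and
transition counts are preserved by cyclic shifts and reversals), which is
likewise asserted.

A formulation of the pyramid as a sum of learnable global and local
convolutions exists alongside the procedural description; the numbered
comparison-based procedure is implemented as normative, with the
"global + local over scales" reading realised by the schedule
concatenation. The descriptor has no learnable parameters.

## 3. The network

A compact residual CNN of depthwise-separable convolutions. Each block
applies a per-channel $k \times k$ spatial convolution ('same' padding)
followed by a $1\times1$ pointwise channel mix: $k^2C + C\,C_t$ weights
instead of $k^2 C\,C_t$ for a standard convolution (`param_count()`
reports both, plus biases and skip projections separately). The block
output is `ReLU(separable(x) + skip(x))` where the skip path is the
identity when shapes match and a strided $1\times1$ projection otherwise.
Default desk-scale capacity: four stride-2 blocks, channels
$16 \to 32 \to 64 \to 128$, input $128\times128\times3$ (tiles are
block-averaged/bilinearly resized to the configured input size), ReLU
activation, global average pooling, dense softmax head.

**Feature grafting.** A custom layer broadcasts the 300-dimensional
texture vector to every spatial location of an intermediate map and
appends it along channels ($C \to C + d$). During backpropagation the
handcrafted branch is a *constant input*: the upstream gradient restricted
to the first $C$ channels flows on, none reaches the descriptor. (The
source formulation subtracts the handcrafted term before differentiation,
which is exactly this reading; its index notation is not internally
consistent, so constant-branch backprop is the one coherent
implementation.) The graft point defaults to *after the final residual
block, before pooling* — "mid-network" placements are configurable via
`graft_after_block`, in which case subsequent blocks consume $C + d$
channels. With the default placement, global average pooling of the
grafted map yields exactly the pooled convolutional channels followed by
the untouched texture vector, i.e. the fused representation itself.

Training (`train_network()`) is minibatch SGD with momentum on the
multinomial cross-entropy: defaults 4 epochs, batch 16, learning rate
0.01, momentum 0.9, chosen for the desk-scale synthetic study (300 tiles
of $128^2$; the classical classifiers on the fused features, not the
softmax head, are the final classifier, so the network needs to be a
feature extractor, not a converged classifier). All forward/backward
passes are hand-vectorised base-R array math; gradients are verified
against central differences in the test suite. Everything is seeded:
initialisation, shuffling, and the classifier fits, so identical
configurations reproduce identical histories and artifacts byte for byte.
A non-finite loss aborts with the epoch and tile named.

## 4. Fusion and evaluation

`extract_fused_features()` returns one row per tile: pooled network
channels (`cnn_*`) then the texture block (`glpp_*`). Classifiers:
RBF SVM (`C = 1`), $k$-nearest neighbours (`k = 5`), CART tree — features
are standardised by train-set mean/sd for the scale-sensitive SVM/KNN.
`evaluate_classifier()` reports the confusion matrix and per-class
one-vs-rest sensitivity, specificity, precision, F1 and trapezoidal ROC
AUC; macro values are unweighted class means (the natural choice for
balanced designs; classes absent from the evaluated labels are reported
as `NA` and excluded from macros). `tidy()`/`glance()` give the per-class
and macro tibbles; `autoplot()` draws the confusion heatmap. Reports
round-trip losslessly through JSON. Both the validation and the test
split are evaluated and written, since summary tables in the literature
do not always say which split they show.

`ablation_compare()` trains once and evaluates three classifier runs on
identical splits: network-only, texture-only, fused. Concatenation fusion
is not a free lunch: z-scoring a block of uninformative dimensions
inflates their contribution to RBF distances, so fusion helps when each
block carries real signal and can dilute when one block is pure noise
with many dimensions — the texture-contrast study in the tests is
constructed so the texture signal is strong and the fused run retains it.

## 5. The synthetic generator

`generate_tiles()` renders seeded H&E-like tiles: a Poisson number of
elliptical nuclei (uniform centres, truncated-normal semi-axes, random
orientation) carrying the nuclear stain with a sinusoidal chromatin
texture at a class-specific frequency, over a smooth low-frequency
stromal field carrying the second stain; the two concentration fields are
pushed through the exact Beer–Lambert map above, integer-rounded, with
optional additive Gaussian sensor noise (default sd 2 levels). Because
rendering uses the same physical model the normalizer assumes, stain
estimation is a genuine parameter-recovery problem with a known answer
(`ground_truth_stains()`), not a fit to an approximation.

The five default classes mirror the balanced five-class colon/lung
layout and differ along the two axes both pathways can read: nuclear
density (malignant 55–70/tile vs benign 14–30) and chromatin frequency
(squamous-like 0.30 cycles/px, adenocarcinoma-like 0.12–0.18, benign
0.03–0.06), with the colon classes using a 6°-rotated stain matrix and a
richer stromal range to emulate a different laboratory. The two benign
classes are additionally separated by nucleus size and stromal
concentration because their stain difference is — correctly — erased by
normalization. These parameters were fixed at design time so that the
default study (60 tiles/class, $128^2$, 70/15/15 stratified split) is
classifiable end to end; they are study conditions, not tuning knobs.

What the generator does *not* emulate: nucleus clustering and gland
morphology, chromatin granularity beyond a single sinusoid, out-of-focus
blur, compression artifacts, pen marks and tissue folds. Passing the
end-to-end checks therefore demonstrates that the pipeline's mechanics —
normalization, descriptor, training, fusion, evaluation, seeding — are
correct and informative on data obeying its physical model; it does not
certify accuracy on real slides.

## 6. Problem sizes and determinism

The shipped study sizes are deliberately desk-scale: 60 tiles/class at
$128^2$ for the end-to-end run (about two minutes), 25 tiles for stain
recovery, $16^2$ images for the exhaustive descriptor oracle, and a
$96^2$/32-input texture-contrast set for the ablation. One global seed
derives per-stage child seeds (`child_seed()`), so stages are
independently reproducible; rerunning a pipeline configuration reproduces
feature CSVs and report JSONs byte-identically, and a completed run
directory refuses to be overwritten without an explicit flag.

## 7. Known limitations

* Pure-R training is adequate only at desk scale; there is no GPU path.
* The stain model is strictly two-stain; tiles with a third chromogen
  violate the unmixing assumptions.
* Uniform-pattern binning at $P > 12$ discards phase information that the
  full histogram would keep at small $P$.
* The svm/knn/tree defaults are the documented canonical settings, not
  tuned values; no hyper-parameter search is provided.
* The weak-annotation label-optimizer used upstream in some workflows
  (external pretrained detectors) is out of scope, as is benchmarking
  against pretrained backbone networks.
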