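---
title: "Methods: segmentation and dose-response phenotyping of C. elegans in microfluidic channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and dose-response phenotyping of C. elegans in microfluidic channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Developmental-toxicity (DevTox) assays read out how chemical exposure
perturbs growth. *C. elegans* is a convenient whole-organism model: a
72-hour exposure from the L1 stage turns into an easily measured body-size
phenotype. The imaging platform this package targets immobilizes one worm
per microfluidic trapping channel — 24 wells, 40 gently tapering channels
each, 960 channels per device — and photographs every channel as a
brightfield z-stack (10 slices, 6 µm apart, 5 time points) plus one
fluorescence z-stack. A channel crop is tall and thin: 5,056 px along the
channel axis and ~354 px (150 µm) across.

The analysis chain is:

1. crop each field of view (8 channels) into per-channel hyperstacks,
   referenced to a fiduciary cross mark;
2. pick the best focal plane per channel and stack the `2N+1` surrounding
   z-slices as input channels of a 2.5D segmentation network
   (`N = 1` by default);
3. jointly segment the worm body and classify the channel
   (full / partial / empty worm);
4. post-process the soft segmentation into per-worm length, area and
   volume, plus gut autofluorescence;
5. aggregate per well, filter outliers, and fit dose–response statistics
   (EC10, LOAEL, control CV).

No public imaging data exists for this device class, so the package ships a
seeded synthetic-scene generator that emulates the acquisition, and every
stage is tested against it.

# The network

`net_init()` builds a U-Net whose encoder and decoder levels are
pre-activation residual blocks (two 3×3 convolutions with group
normalisation and ReLU, plus an identity or 1×1-projected skip). Level
$\ell$ halves the spatial grid, so with $L$ levels the bottleneck grid is
$(H/2^L) \times (W/2^L)$; at the default $L = 4$, a 5,056 × 384 input gives
a 316 × 24 grid of 256-dimensional features.

Instead of a convolutional bottleneck, the grid is flattened (row-major, y
outer) into a token sequence, learnable positional encodings are added, and
a small pre-norm vision transformer (default 4 blocks, 8 heads, feed-forward
expansion 4) lets features communicate across the full worm axis — the body
spans thousands of pixels, far beyond any convolutional receptive field at
this depth. Two heads consume the tokens:

* the **decoder** mirrors the encoder (2×2 transposed convolutions, skip
  concatenation, residual blocks) and ends in 1×1 convolutions and a
  per-pixel softmax over {background, worm};
* the **classifier** pools the tokens by attention with a single learned
  seed vector and maps the pooled vector through linear layers to
  full/partial/empty probabilities.

The "2.5D" convention means the `2N+1` z-planes enter as input channels of
2D convolutions: the network sees volumetric context without 3D kernels.

The implementation is native R with hand-derived backpropagation for every
layer (convolution via compiled im2col/col2im kernels, group and layer
normalisation, multi-head and pooled attention, GELU, dropout), AdamW, and
the two learning-rate schedules. Analytic gradients are verified against
central finite differences in the test suite at machine precision. Design
choices the architecture description leaves open, and how this
implementation resolves them:

* attention heads: 8 (256/8 = 32-dimensional heads, standard practice);
* normalisation inside conv blocks: group normalisation (batch size
  independent; the group count is reduced to the largest divisor of the
  channel count), selectable to `"none"`;
* downsampling by strided 3×3 convolution, upsampling by 2×2 transposed
  convolution (both learnable);
* two segmentation classes — ground-truth polygons collapse to a single 2D
  binary mask, so the softmax is over background/worm;
* blocks are pre-activation, so a block with zeroed convolution weights is
  an exact identity — a property the tests exploit.

Full-scale inputs (7,584 bottleneck tokens) are practical on a GPU; on CPU
this implementation is intended for reduced geometries, and all shape
contracts are tested at toy sizes as well.

# Training

`train_config()` carries the base recipe: mini-batches of 32, AdamW with
initial learning rate 2×10⁻⁴ and weight decay 10⁻², cosine annealing with
warm restarts (first period $W_0 = 10$ epochs, period multiplier $F = 2$,
restarts therefore at epochs 0, 10, 30, 70, 150, …) over 1,200 epochs, and
an 8:1:1 stratified train/validation/test split whose per-class proportions
stay within one sample of the global mix. Augmentation applies horizontal
and vertical flips, small rotations (±5°, nearest-neighbour with
edge-replication fill) and gamma contrast adjustments in [0.7, 1.3]; the
geometric transforms hit image and mask identically.

The loss is $w_{seg} L_{seg} + w_{cls} L_{cls}$ with both weights 1 by
default. $L_{cls}$ is 3-way cross-entropy for every sample. $L_{seg}$ —
soft-Dice plus mean pixel cross-entropy, equally weighted — is computed
only for full-worm samples (only those carry a mask; partial worms are not
annotated), and the tests verify that decoder gradients are exactly zero on
batches without full worms. The loss functions themselves are a design
choice: the recipe names none, and Dice+CE is the standard pairing for
thin-structure segmentation. Model selection keeps the checkpoint with the
highest validation Dice; the floor of the cosine schedule is `lr0/1000`
(unstated upstream; any small value behaves equivalently).

Few-shot fine-tuning (`finetune_few_shot()`) adapts a trained model to a
phenotypically shifted population (smaller, lower-contrast worms from the
4-layer chip variant). The corpus mixes the `n_new` new-domain samples with
an equal number of original-domain samples to avoid catastrophic
forgetting, and trains with a one-cycle cosine schedule over 250 epochs.
The printed maximum learning rate for this phase is 10⁻⁶, which is
unusually small for AdamW; it is implemented exactly as printed but exposed
as configuration, and the scaled-down experiments in this package use a
rate suited to their problem size (see below).

# The synthetic scene generator

`scene_config()` defaults to the acquisition geometry above; the pixel
size defaults to 150/354 ≈ 0.424 µm so that a 150 µm channel section spans
354 px. `make_worm()` draws a sinusoidal centerline whose numerically
integrated arc length matches the requested body length to 0.5%, with a
width profile tapering to zero at head and tail; `rasterize_worm()` stamps
disks of the local radius along the centerline. Full worms sit clear of the
channel ends, partial worms are translated across an end, empty channels
have no worm — and the sidecar class label is derived from exactly that
geometry, so ground truth is consistent by construction. Brightfield
rendering darkens the worm interior against the channel background, adds
granule-like internal texture and an edge band (the in-focus high-frequency
content), then blurs each z-slice with a Gaussian whose σ grows linearly
with distance from the focal plane — the simplest defocus model under which
Laplacian-energy focus selection provably recovers the focus index — and
adds seeded Gaussian noise. Small debris specks are rendered outside the
worm and kept below the phenotype module's component-size threshold.

Fluorescence stacks place punctate granules only in the gut region
(central 60% of the centerline, inner 50% of the width — the intestine is
medial), with mean granule intensity following an increasing Hill curve of
dose. `make_device_dataset()` assembles a full device: wells = doses ×
replicates, 5 FOVs × 8 channels per well, per-worm lengths drawn as
Normal(µ(dose), cv·µ(dose)) from a decreasing Hill curve
(defaults: top 1100 µm, bottom 600 µm — control adults down to arrested
early-L4 sizes — EC50 2 µM, biological CV 4%, matching a methylmercury-like
exposure of 0.5–9 µM plus solvent control).

What the generator does **not** emulate: realistic optics (PSF shape, shot
noise, vignetting), egg/embryo phenotypes, worm motion between time points,
and the full diversity of debris. Passing tests therefore demonstrate that
the algorithms are correct against a controlled image model, not that the
shipped default network weights would transfer to real micrographs — on
real data the network must be trained on real annotations, which the
training module supports unchanged.

# Morphometry

Inference thresholds the worm probability at 0.50 (ties count as
foreground), strips the width padding, and keeps the single largest
8-connected component if it reaches the minimum area (default 2,000 px at
the native pixel size — well below any L4 worm, well above eggs and debris;
scale it with the pixel size). One worm per channel is a property of the
device, hence the largest-only rule.

Body length is measured on the morphological skeleton (Zhang–Suen
thinning): the longest geodesic through the skeleton's 8-neighbour graph,
with axial steps weighing 1 px and diagonal steps √2 px. Two corrections
matter at this point. A pixel-geodesic zigzags around a smooth curve and
systematically overestimates its length (up to ~8% depending on
orientation), so the longest path's coordinates are smoothed with a short
moving average (reflection-padded, window 9 px) before measuring; and
thinning erodes the skeleton away from the tapered tips, so each end of the
path is extended along its end direction to the mask boundary. On synthetic
worms of known arc length the corrected estimate is accurate to ~1%; the
raw geodesic remains available (`smooth = FALSE`) and is tested for exact
agreement with a brute-force all-pairs shortest-path oracle.

Area is the foreground pixel count times the pixel area. Volume assigns
every mask pixel the height of the channel layer at its axial position —
the channels taper in discrete layers, so height is a piecewise-constant
lookup relative to the fiduciary mark (`channel_geometry()`; the "3L" and
"4L" presets carry nominal layer heights and must be calibrated against
the actual chip drawings before absolute volumes are interpreted). An
alternative reading — local worm thickness rather than channel height —
would underestimate less for thin worms in tall layers, but the
channel-height reading is the one consistent with the position-referenced
geometry lookup, and is what is implemented.

# Autofluorescence

Gut granules dominate the stress-induced autofluorescence signal. The
pipeline takes a maximum-intensity projection over z, derives a threshold
from the solvent-control wells — the 95th percentile (type-7 quantile,
pooled over all control in-mask pixels) so that the brightest 5% of control
pixels lie above it — and averages the in-mask pixels strictly above that
threshold. "Above" is read as strict; pixels exactly at the threshold are
excluded. The mean is normalised per unit body length and per unit body
area. The phrase "average autofluorescence per unit body length" admits an
integrated-intensity reading (sum rather than mean); the mean is the
default and the sum is available behind `integrate = TRUE`. The threshold
is recomputed from each run's own controls, mirroring per-experiment DMSO
normalisation.

# Dose–response statistics

Per-worm values are filtered with Tukey fences (1.5 × IQR, type-7
quartiles) on body length and on autofluorescence per unit length; a worm
outside either fence is removed entirely. Remaining worms give well means,
SDs, SEMs and CVs, and the control CV across replicate wells is the
reproducibility figure of a run.

The dose–response model is the 4-parameter variable-slope Hill function
$Y = Bottom + (Top - Bottom)/(1 + (X/EC_{50})^h)$, fitted by
Levenberg–Marquardt least squares with EC50 parameterised on the log scale.
For body endpoints the Bottom is constrained to 0; for autofluorescence all
four parameters are free. (The source text for this constraint is
grammatically ambiguous — "constrained to zero … and left unconstrained,
respectively" — and this reading, Bottom = 0 for body endpoints, is the one
implemented and flagged here as an interpretation.) Controls enter the fit
through a dose substitution $X_0 = \min(\text{dose}>0)/100$, the standard
placement of a zero dose on a log axis; the substitution factor is
configurable. EC10 follows from the "EC-anything" transform
$EC_f = (f/(100-f))^{1/|h|} \cdot EC_{50}$, which reduces to EC50 at
f = 50 for any slope.

The 95% CI on EC10 is a normal-theory delta-method interval on log(EC10)
from the LM covariance — chosen over profile likelihood because it is fast
enough to run inside calibration simulations, and its coverage at the
assay's design (12 doses × 5 replicates, 5% CV) measures ≥ 80% in the
seeded simulations shipped with the package; a parametric bootstrap
(`ci = "bootstrap"`) is available when the asymptotic interval is suspect.

LOAEL: Shapiro–Wilk normality p-values are reported per group but do not
change the test (the procedure stays Welch-based regardless); a Welch
heteroscedastic ANOVA (Welch's F with Satterthwaite-style denominator df,
implemented from the published formulas and cross-checked against
`stats::oneway.test`) is followed by Dunnett T3 comparisons of each dose
against control — pairwise Welch t statistics with Satterthwaite df,
adjusted by the studentized maximum modulus over the number of comparisons.
The SMM tail uses its closed form $1 - (2F_\nu(t) - 1)^m$; a seeded
Monte-Carlo tail is available. Because the comparisons share the control
sample, the adjustment is mildly conservative: the simulated family-wise
type-I error at nominal 0.05 is ≈ 0.04. The LOAEL is the smallest dose with
adjusted p < 0.05.

# Problem sizes used in tests and the acceptance script

The shipped experiments run on one CPU at reduced geometry, chosen once as
the package's scaled-down study design:

* scene 96 × 48 px at 4 µm/px, 5 z-slices, 1 time point; worm widths are
  drawn at 15% of body length so the width in pixels (~10 px) stays in a
  realistic regime at the coarse pixel pitch;
* network: 2 encoder levels, 8 base features, 32-dimensional bottleneck,
  1 transformer block, 4 heads;
* overfit check: 8 labeled channels (6 full, 1 partial, 1 empty),
  120 epochs, AdamW at 10⁻³ with warm restarts — reaches training Dice
  > 0.95;
* few-shot check: base domain = large high-contrast worms, shifted domain =
  small low-contrast worms; 8 shifted samples mixed 1:1 with base samples,
  one-cycle at max 3×10⁻⁴ over 40 epochs (the printed 10⁻⁶ is a no-op at
  this scale) — shifted-domain Dice rises by several points while
  base-domain Dice moves by less than 2 points;
* statistics: 200 seeded Hill-recovery simulations at the 12-dose ×
  5-replicate design, 400 null simulations for the LOAEL type-I rate.

# Known limitations

* The native network is CPU-bound and meant for reduced geometries and
  methodological work; full-scale (5,056 × 384, 1,200 epochs) training
  expects a GPU implementation of the same architecture.
* Skeleton-length corrections are calibrated on smooth synthetic bodies;
  strongly self-occluding or coiled worms (which the channel geometry is
  designed to prevent) would violate the single-path assumption.
* The geometry presets carry nominal layer heights; absolute volumes
  require chip calibration.
* Hill fits with Bottom fixed at 0 are biased when the true response floor
  is far from zero (arrested-but-alive larvae); this mirrors the assay
  convention rather than a statistical optimum, and the unconstrained mode
  is one switch away.
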