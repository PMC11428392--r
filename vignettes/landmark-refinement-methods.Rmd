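---
title: "Anatomically constrained landmark localization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomically constrained landmark localization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `gaffa`, the parameters
that matter, what the synthetic data generator does and does not emulate,
and the numerical and design decisions taken where the problem left room.
It states no empirical numbers: every quantitative claim the package makes
is computed by its test suite or by `scripts/acceptance.R` at run time.

## The problem

Anatomical landmark localization (ALL) predicts the pixel coordinates of
named anatomical points — here the 37 landmarks of a hand radiograph
configuration (13 wrist/carpal points and five finger chains). Deep heatmap
regressors solve most of the problem but occasionally produce *outliers*:
predictions far from the truth caused by locally similar structures or
out-of-distribution inputs (occlusions, cut-offs). Because downstream
clinical tasks consume every landmark, outlier robustness matters more than
the last fraction of a millimetre.

The package couples a compact U-Net localizer with three refinement
paradigms:

1. **GAFFA** — a differentiable layer that approximately solves a Markov
   random field (MRF) over landmark positions with a single sum-product
   iteration in log-energy space, using conditional displacement priors
   estimated from annotated training data. Trained end-to-end with the
   localizer.
2. **SpatialConfiguration-Net (SCN)** — an implicit alternative: a coarse
   learned spatial filter multiplied into the local heatmaps.
3. **Graphical model (GM)** — an explicit, non-differentiable
   post-processing step: blob candidates scored by t-distribution distance
   and distance-ratio costs, solved with loopy belief propagation.

## Physical scale and metrics

Hand radiograph collections usually lack physical resolution metadata.
The package adopts the standard convention of declaring the wrist — the
segment between landmarks 2 and 6 — to be 50 mm wide, giving a per-image
scale \(s = 50 / \lVert l_2 - l_6 \rVert_2\) in mm/px. Point-to-point errors
are Euclidean distances multiplied by \(s\). Summaries report median, mean
and standard deviation plus outlier counts and percentages beyond 2, 4 and
10 mm. Two conventions the literature leaves open are fixed here:

* **Sample standard deviation** (`ddof = 1`); at the relevant sample sizes
  (tens of thousands of predictions) the population/sample difference is
  negligible, and sample SD is the common choice in comparison tables.
* **Strict outliers**: an error exactly equal to the radius is *not* an
  outlier ("exceeding" the radius).

## Heatmap regression

Targets are blobs centred on each landmark: Gaussian
\(\gamma e^{-d^2/2\sigma^2}\) (default \(\sigma = 3\) px) or Laplacian
\(\gamma e^{-d/\sigma}\), scaled by \(\gamma = 1000\). Blobs are evaluated
over the whole frame with no cutoff radius (the training path cuts the
evaluation window at 8\(\sigma\), where the Gaussian tail is below the
double-precision rounding of the peak). Decoding is either the intensity
argmax (ties broken at the first row-major position, so results are
deterministic) or a differentiable soft-argmax: the heatmap is turned into
a spatial distribution and the expected pixel coordinate returned.

**Soft-argmax normalization.** For non-negative heatmaps the map is clamped
at zero and divided by its sum. This makes the documented limits exact: a
one-hot map decodes to exactly that pixel, a uniform map to the exact frame
centre, and a rendered blob agrees with its argmax to well below
\(10^{-3}\) px. A softplus-floor rectification was considered and rejected:
its strictly positive background adds a centre-of-frame bias that breaks
those exact limits. Log-domain energy maps (which can be negative
everywhere) are decoded with a softmax instead — mathematically this is the
same linear expectation applied after leaving log space, and it is smooth
in the energies, which is what end-to-end training needs.

The U-Net follows the classic encoder–decoder layout: two 3×3
convolutions per level (convolution → batch normalization → leaky
rectification with slope 0.1 → dropout), 2×2 average pooling, fixed
bilinear upsampling, and channel-concatenated skip connections (the first
decoder convolution of each level therefore takes `2 * width` maps). The
reference capacity is 4 levels × 128 channels with dropout 0.3; the scaled
synthetic study uses a small instance (3 levels × 8 channels, no dropout)
— see *Study sizes* below. Two engineering choices that are invisible in
the equations:

* **Output scaling**: the final convolution output is multiplied by a fixed
  constant equal to the blob peak \(\gamma\), and its weights start near
  zero. The convolution stack then regresses order-one values. Without
  this, per-parameter update clipping in Adam makes the climb to a peak of
  1000 take tens of thousands of steps.
* **"Same" zero padding** everywhere, so every level preserves its spatial
  size; Kaiming fan-in initialization.

## The MRF and its topology

The refinement methods share an undirected graph over the 37 landmarks.
The shipped default encodes the wrist/carpal chain (1–13), the five finger
chains from metacarpophalangeal joint to fingertip (thumb: 18–21, four
landmarks; other fingers five), attachments of the metacarpal row to the
carpal chain, and rung edges between corresponding joints of adjacent
fingers. The exact carpal wiring is a convention — the method only needs a
connected, anatomically plausible graph — and any dataset can supply its own
edge list.

The *global set* (wrist pair, the five metacarpophalangeal joints, the five
fingertips — 12 landmarks) is added to every landmark's neighborhood
regardless of direct edges. This is what makes the refinement robust to
occlusion: even when a landmark's whole local neighborhood is erased, global
landmarks still send messages. A landmark never messages itself.

## Conditional displacement priors

For an ordered pair \((i, j)\), the prior \(p(i\,|\,j)\) is the spatial
density of landmark \(i\) after translating landmark \(j\) to the centre of
a frame *twice* the image size (doubling accommodates every displacement
that fits the source frame). Densities are full-covariance Gaussian
mixtures fitted to training coordinates; each training image is sampled
three times under the spatial augmentation (translation, rotation, elastic
— intensity and occlusion perturbations do not move landmarks), so the
priors match what the localizer sees in training. The component count
(up to 10) minimizes the mean of AIC and BIC, with ties going to fewer
components; a ridge of \(10^{-3}\) px\(^2\) on the covariance diagonal
protects degenerate clusters. Rasterized grids are left unnormalized: the
refinement treats them as energies, and the tests assert that rescaling a
prior leaves initial argmax decisions unchanged.

## The differentiable sum-product refinement

For landmark \(i\) with neighborhood \(N_i\),

\[
\widehat{me}_i \;=\; me_i \;+\; \sum_{j \in N_i}
\log\!\big( \mathrm{sp}_\beta(p_{i|j}) \ast \mathrm{sp}_\beta(p_j)
  + \mathrm{sp}_\beta(b_{j\to i}) + \epsilon \big),
\qquad me_i = \log \mathrm{sp}_\beta(p_i + \epsilon),
\]

with \(\mathrm{sp}_\beta(x) = \log(1 + e^{\beta x})/\beta\), \(\beta = 5\),
\(\epsilon = 10^{-6}\), \(\ast\) true convolution, and \(b_{j \to i}\) a
learnable bias grid initialized at \(\epsilon\). The log-sum replaces the
product of one sum-product iteration for numerical stability; the softplus
keeps every convolution input positive; no exponentiation back from log
space is performed because the maximum location is unchanged.

Numerical and design choices:

* **Kernel alignment.** The conditional kernel has twice the extent of the
  map it convolves and its origin sits at its exact centre pixel; a delta
  kernel at displacement \(d\) shifts the map by exactly \(d\) (asserted by
  test). Zero-padded linear convolution with a centred crop is used —
  circular wrap-around would leak energy across the frame.
* **Resolution pipeline.** Localization heatmaps are batch-normalized
  (per-landmark channels, affine), bicubic-downsampled by `downFactor`
  (power of two); kernels are stored another `kernelStoreFactor` coarser
  and bicubic-upsampled before each convolution to bound the learnable
  parameter count; the message sum is bicubic-upsampled back to full
  resolution before the addition with \(me_i\), which is always computed at
  full resolution so the localizer's accuracy is preserved.
* **Convolution realizations.** The exported `messageConvolve()` offers a
  Fourier-domain product, a dense-Toeplitz/BLAS path and a literal
  nested-loop sum; the tests pin all three to each other at \(10^{-5}\),
  and the full layer is pinned against a nested-loop transcription of the
  energy equation.
* **Training.** Joint loss = heatmap MSE + \(\lambda\,\times\) coordinate
  MSE of the soft-argmax decodes, with \(\lambda\) set once from the
  first-batch loss ratio and frozen. Kernels, biases and the heatmap batch
  normalization all receive gradients; a freeze switch holds the kernels at
  their prior initialization for ablations. Inference uses running
  batch-norm statistics.

## SCN and graphical-model comparisons

The SCN head average-pools the local heatmaps into a coarse space, applies
three successive 7×7 convolutions (batch normalization before each
activation, final layer linear) without internal downsampling, upsamples
the resulting spatial filter bilinearly and multiplies it into the local
heatmaps elementwise. The factorization `output = local × filter` is exact
and tested.

The graphical model extracts blob candidates per landmark with multiscale
Laplacian-of-Gaussian detection (scales 2–4 px, matching the blob width),
ranks them by heatmap peak intensity, keeps the top 25 and discards
normalized peaks below 0.015. Pairwise costs combine (a) the log-density of
the candidate-pair distance under a location-scale t-distribution fitted to
training distances per edge, and (b) ratio costs against the three edges
with the lowest fitted scale: the distance is rescaled by
\(\mu_{\mathrm{ref}} / d_{\mathrm{ref}}\) and scored under the edge's own
t-distribution, averaged over the three references — a realization chosen
here (the ratio comparison is under-specified in the literature this
mirrors) and isolated behind one function. The two cost families are
rescaled to equal empirical spread per image ("equally important"). The
MRF is solved by synchronous loopy belief propagation with damping 0.5,
up to 100 iterations, convergence at \(10^{-6}\); on trees this reproduces
exact marginals (tested against brute-force enumeration). Non-convergence
returns current beliefs with a warning rather than failing.

## Occlusion protocols

*Training-time*: one rectangular box per batch (area 1–15 % of the frame,
aspect ratio 0.5–2 — the aspect range is a convention chosen to avoid
degenerate slivers), filled with i.i.d. uniform noise in each image's
intensity range, at the same location in every image of the batch. Targets
are never modified.

*Test-time*: each finger is selected with probability 1/5; within a
selected finger a contiguous distal suffix of joint pairs is occluded
(including the empty suffix), matching an amputation-like pattern; a
uniform-pair alternative is available by flag. A segment is erased by a
chain of circles: \(c = \lfloor \lVert v \rVert / r \rfloor\) circles of
radius \(r\) (10 px at 256, scaled proportionally) at steps \(v / c\),
indices \(0 \dots c\) so both endpoint joints are covered and the circles
overlap into a connected strip; intensities are zeroed plus Gaussian noise
(sd 0.02). Metrics are averaged over repeated seeded runs (30 by default),
with outlier counts averaged and percentages recomputed from averaged
counts.

## The synthetic hand generator

The generator exists so priors are learnable and occlusion tests are
meaningful without external data. A hand-designed 37-landmark template on a
256² frame (wrist pair at a nominal 50 px separation, so the physical scale
works out to roughly 1 mm/px) receives a global affine perturbation
(rotation within ±0.15 rad, scale 0.9–1.1, translation ±10 px) plus
per-landmark jitter (sd 1.5 px); bones are rendered as soft capsule ridges,
joints as Gaussian bumps, plus background noise (sd 0.05). Three-fold
splits mirror the common cross-validation protocol.

What it does *not* emulate: radiographic texture, growth-plate appearance
changes, overlapping soft tissue, annotation error, or inter-subject shape
variation beyond affine-plus-jitter. Passing the end-to-end tests therefore
demonstrates that the pipeline's mechanics work — priors concentrate where
they should, messages rescue occluded landmarks, training converges — not
that clinical-grade accuracy would transfer to real radiographs.

## Study sizes and the compute budget

The end-to-end study trains two models (localizer alone, and jointly with
the refinement layer) on 40 of 60 synthetic images at 128² and evaluates
on the held-out 20, including ten occlusion-protocol runs per model. The
shipped study size — 45 epochs, batch 8, learning rate 2×10⁻³, a
3-level × 8-channel localizer, refinement at working resolution 16 with
kernels stored at 16² — was chosen so the whole study completes in roughly
a quarter of an hour on a single CPU; it is the package's own scaled-down
protocol, with the reference protocol (800 epochs, 128 channels, batch 8,
learning rate 10⁻³, dropout 0.3) kept as the documented defaults of the
individual configuration objects. Training runs on a single-precision
engine with persistent workspaces that replicates the double-precision
reference implementation step for step (asserted by a parity test);
inference and evaluation always run through the reference code.

Other numerical choices: bicubic resampling uses the Catmull-Rom kernel
with pixel-area alignment (endpoint-aligned for the elastic control grid);
the elastic deformation is applied as a backward warp and landmark
coordinates are mapped by numerically inverting that warp with a
fixed-point iteration, which keeps painted markers and transformed
landmarks within a pixel of each other; batch normalization uses batch
statistics in training and running statistics at inference.

## Known limitations

* The graphical model's ratio-cost formula and the equal-importance
  weighting are conventions; they are isolated in one function each for
  revision.
* The refinement layer's accuracy gain is bounded by the kernel storage
  resolution; very coarse kernels blur the anatomical constraint.
* The synthetic generator's affine-plus-jitter shape model understates real
  anatomical variation; component counts selected for its priors are
  typically 1–3, whereas richer data may need more.
* Training the SCN head end-to-end is supported through the
  double-precision reference engine only.
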