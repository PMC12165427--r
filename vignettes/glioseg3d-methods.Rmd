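---
title: "glioseg3d: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glioseg3d: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`glioseg3d` segments glioma compartments in multimodal 3D brain MRI with an
improved 3D U-Net. This vignette is the package's own account of the science
it implements: the model and its assumptions, the parameters that matter,
what the synthetic data generator does and does not emulate, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The segmentation problem

Gliomas appear on MRI as heterogeneous lesions with three nested
compartments, coded with the BraTS label convention: necrotic and
non-enhancing core (NET, label 1), peritumoral edema (ED, label 2), and
enhancing tumor (ET, label 4), on a background of 0. Evaluation follows the
standard region decomposition — whole tumor WT = {1,2,4}, tumor core
TC = {1,4}, enhancing tumor ET = {4} — because the clinically relevant
questions (extent, core burden, active rim) live at the region level. Four
co-registered modalities (T1, T1C, T2, FLAIR) are stacked as input channels
in that fixed order; internally label 4 is remapped to class index 3 and
mapped back at the I/O boundary.

## Network

The model is an encoder–decoder over 3D feature maps:

* **Residual encoder.** Each level applies two 3×3×3 convolutions with
  Instance Normalization and Leaky ReLU plus an identity (or 1×1×1
  projection) shortcut. Downsampling is a stride-2 3×3×3 convolution
  followed by dropout; `depth = 4` halvings leave the bottleneck 16× smaller
  per axis than the input. Instance Normalization replaces batch
  normalization throughout because training runs at batch size 1.
* **ASPP bottleneck.** Five parallel branches — a 1×1×1 convolution, three
  3×3×3 atrous convolutions with dilation rates 6/12/18, and a global
  average pooling branch (pooled vector → linear layer → broadcast) —
  concatenated on channels and projected back by a 1×1×1 convolution. The
  dilation triplet trades receptive-field diversity against the small
  bottleneck grid; with "same" padding it degrades gracefully on tiny grids.
* **MFAB skip fusion.** On each skip connection, the upsampled decoder map
  is aligned to the skip's channel count by 1×1×1 then 3×3×3 convolutions;
  global average pooling of both maps feeds two separate two-layer
  fully-connected bottlenecks (reduction ratio `se_reduction = 4`, ReLU
  inner activation) whose outputs are summed and squashed by a sigmoid into
  per-channel scales β ∈ (0,1). The *skip* features are rescaled by β,
  added to the aligned decoder map, and refined by two further 3×3×3
  convolutions. This is squeeze-excitation-style channel recalibration
  driven jointly by low-level (edge-rich) and high-level (semantic)
  statistics; its purpose is to suppress irrelevant background channels in
  the encoder output before fusion. A diagnostic `attention_bypass` flag
  forces β ≡ 1, which reduces the block exactly to its convolutional
  pathway — the property the test suite checks.
* **Deep supervision.** A 1×1×1 head at every decoder resolution produces a
  class map; all heads are trilinearly interpolated to full resolution and
  summed with equal weight before a single softmax. Upsampling everywhere is
  trilinear interpolation followed by convolutions, avoiding the
  checkerboard artifacts of transposed convolutions.

Channel widths start at `base_channels` (16 at desk scale, 32 for full
runs) and double per level; per-level widths and block counts are not
uniquely determined by the architecture's published description, so they
are explicit configuration with these defaults. The attention equations as
published contain an inconsistency (the second bottleneck reuses the first
branch's weight symbol and stacks two ReLUs); the implementation treats the
two branches symmetrically — two distinct weight pairs, ReLU inside,
sigmoid once after merging — which is the canonical squeeze-excitation
form consistent with the rest of the block.

### Why there is a hand-rolled autodiff

No deep-learning runtime ships with the target environment, so convolutions
and their gradients are computed directly: an im2col/col2im pair in C++
reshapes each 3D convolution into a BLAS matrix product, feature maps are
voxels×channels matrices, and a small reverse-mode tape composes layers.
Analytic gradients are verified against central finite differences
end-to-end in the test suite. This is a deliberate scope decision: the
network *is* the contribution, so it is authored, not wrapped.

## Loss

The objective combines a Tversky-form soft-Dice term with a Focal term:

L = [B − Σ_b TP_b/(TP_b + α·FN_b + β·FP_b + ε)] − (λ/N)·Σ_b Σ_n g·(1−p)²·log p

with soft counts TP = Σ p·g, FN = Σ (1−p)·g, FP = Σ p·(1−g) over all N
voxels and B classes including background. α and β trade false negatives
against false positives; λ balances the two terms. None of the three values
is prescribed by the method's published description, so the defaults are
α = β = 0.5 (which reduces the Tversky form exactly to soft Dice — an
algebraic identity the tests exploit as an oracle) and λ = 1, all exposed
in `loss_config()`. The logarithm is natural by default ("lg" in the
published formula is read as the conventional Focal-loss log; base 10 is a
config switch). The exponent is fixed at 2. Probabilities are clamped to
[1e−7, 1−1e−7] before the log and denominators carry ε = 1e−6, so L is
finite and non-negative, vanishing only at a perfect prediction. The loss
attaches to the fused full-resolution output only; intermediate
deep-supervision heads receive no separate loss term.

## Preprocessing

* **Registration** minimizes MSE between a warped moving image and a fixed
  reference, regularized by the squared-gradient smoothness energy of the
  dense displacement field, by gradient descent (demons-style): the
  similarity gradient is Gaussian-smoothed (σ = 2 voxels) each iteration and
  step-size backtracking enforces a non-increasing objective. Convention:
  `warped(v) = moving(v − d(v))`, so `d` points from moving content to its
  fixed-space position, in voxel units; intensities are min-max normalized
  internally so the objective ignores global scaling. Known-shift recovery
  is validated on a Gaussian blob; the recovered displacement is averaged
  over the blob's support because the background carries no image gradient
  and therefore no registration signal.
* **Normalization** is z-score over the brain mask, truncated to [−5, 5]
  and affinely mapped to [0, 1]; the masked mean lands exactly on 0.5.
* **Noise estimation** uses the variance of the 6-neighbour Laplacian
  residual over the mask interior; for i.i.d. Gaussian noise the Laplacian
  has variance 42σ², giving D = k·σ² with k ∈ [0.1, 10].
* **Stochastic resonance.** Each voxel's normalized gray value A drives a
  bistable system dx/dt = x − x³ + A·sin(ωt) + √(2D)·ξ(t), integrated by
  Euler–Maruyama (dt = 0.01, horizon T = 100, x₀ = A, ω initial 1); the
  terminal state is the processed value. Axial slices are raster-scanned
  row-major to 1D and back. Terminal states live near the ±1 wells, so they
  are mapped affinely to [0,1] before evaluation. A PSNR gate accepts the
  processed volume only if it improves on the input; otherwise a small grid
  of (D, ω) candidates (3 × 2 by default) is searched and the gate falls
  back to the identity, making the reported gain non-negative by
  construction. On real data no clean PSNR reference exists — the input
  itself is used, which turns the gate into a no-degradation guard; the
  clean phantom serves as a true reference only in synthetic tests.
* **Bias correction** is an interface hook: the established N4 algorithm
  can be plugged in via `external_fn`; the built-in fallback fits a
  degree-2 polynomial to log-intensities with Tukey-reweighted least
  squares (to resist tissue outliers such as tumor compartments) and
  divides it out. This fallback is deliberately modest — it is a stand-in
  for a cited external method, not a reimplementation of it.
* **Crop/resample** crops to the padded bounding box of the brain mask and
  resamples trilinearly (intensities) / nearest-neighbour (labels) to the
  target grid, preserving the label set exactly.

## Training

Adam with learning rate 1e−3 and weight decay 1e−4 (the published "L2
regularization" and "weight decay" are treated as the single standard
Adam weight-decay mechanism), batch size 1, cases cycled in seeded order;
the run is bit-reproducible given a seed since dropout defaults to 0.
`split_dataset` performs the 80/20 seeded shuffle split. The desk-scale
capacity check trains the default network on 4 phantoms at 32³ for at most
200 steps and requires the loss to fall below 25% of its initial value with
WT Dice ≥ 0.7 on the training phantoms — an overfitting test of gradient
correctness and capacity, not a generalization claim.

## The phantom generator: what it does and does not establish

`generate_phantom()` builds a brain sphere containing three nested
ellipsoids mapped to labels: innermost → necrotic core (1), middle shell →
enhancing rim (4), outer shell → edema (2). This ordering makes ET the
thin shell — the structure that is genuinely hardest to segment in practice
because of its small volume. Each modality channel is a per-tissue
mean-intensity map (defaults chosen for the canonical contrasts: rim bright
on T1C, edema bright on FLAIR/T2, core dark on T1) times a smooth
multiplicative degree-2 polynomial bias field (mean exactly 1, amplitude
±10% by default), plus i.i.d. Gaussian noise (σ = 0.03 on a [0,1]-ish
intensity scale — a moderate-quality acquisition). Spacing is 1 mm
isotropic. All randomness flows through one seed per case and the seed is
recorded in the export manifest.

What it emulates: nested compartment topology, co-registered multi-channel
structure, label coding, intensity inhomogeneity, additive noise. What it
does **not** emulate: anatomy (no tissue interfaces, gyri, ventricles),
partial-volume effects, multifocal or irregular tumors, modality-specific
noise statistics (Rician), motion/ghosting artifacts. A green test
therefore establishes that the implementation is correct and has the
claimed capacity on data with the right structure — not that the published
BraTS-scale accuracy is reproduced. The headline multi-dataset results are
explicitly out of scope at desk scale.

## Numerical and interface choices

* Coordinates are 0-based voxel indices in (x, y, z) axis order matching
  the NIfTI affine; displacements are in voxels; crop boxes are 0-based
  half-open.
* Trilinear resize uses the half-pixel-center convention
  (`src = (dst + 0.5)·(in/out) − 0.5`, clamped), the same mapping forward
  and in its adjoint.
* HD95 extracts boundaries by 6-connectivity erosion difference and takes
  the 95th percentile of pooled symmetric surface distances with linear
  interpolation, in physical units. Published HD95 numbers for this method
  are internally inconsistent and unit-free, so none is treated as a
  reproducible target; the implementation is validated against a
  brute-force all-pairs oracle instead.
* Overlap metrics define both-empty masks as a perfect score so that
  correct predictions on tumor-free volumes are not penalized.
* NIfTI-1 I/O is implemented directly (348-byte header, sform affine,
  common datatypes, gzip via connections) because no NIfTI package exists
  in the supported dependency set; it is cross-validated against nibabel.
* Configuration is a JSON tree mirroring the CLI flags (no YAML parser in
  the supported set); unknown keys fail fast. Pipeline runs are cached by
  stage markers and fully logged (seeds included) as JSON-lines.
* BLAS threading: the conv gemms are small and suffer badly from thread
  oversubscription on constrained CPUs; tests and scripts pin
  `OPENBLAS_NUM_THREADS=1`.

## Known limitations

* Batch size is fixed at 1 (no batching dimension in the tape); this
  matches the Instance-Norm design but makes training wall-clock-bound.
* The demons-style registration is validated for small smooth
  displacements; large deformations would need a multi-resolution schedule
  it does not have.
* The ASPP rates 6/12/18 are nearly equivalent on very small bottleneck
  grids (padding dominates); they matter at the full 128³ scale.
* Whether ASPP should also feed every skip connection is ambiguous in the
  published description ("applied in the contraction path"); it is placed
  at the bottleneck only.
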