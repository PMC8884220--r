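---
title: "Multi-focus fusion of undersampled z-stacks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-focus fusion of undersampled z-stacks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stackfuse)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The acquisition model

A z-stack is an ordered series of RGB focal planes of one lateral field,
plane 1 shallowest, spaced by a fixed axial step (µm). Two closed forms
describe the geometry of high-NA brightfield acquisition:

* depth of field `DoF = λ / NA²` (`depth_of_field()`): ≈ 0.27 µm for green
  light under a 100x/1.4NA oil objective;
* planes required to cover a slab of thickness St at half a DoF per step,
  `Np = ceil(St · NA² / 2λ)` (`required_planes()`): 7 planes for a 3.5 µm
  thin film.

Undersampling is modelled by `decimate_stack(stack, k)`, which keeps planes
k, 2k, 3k, … (count `floor(D/k)`, step `k × axial_step`). This retention
rule is the only simple one that simultaneously maps 14 planes to 7 (k = 2),
14 to 3 (k = 4) and 7 to 3 (k = 2) — the three regimes the fusion is meant
to bridge. White balancing divides each plane, per channel, by an
empty-field reference normalised to its channel mean (flat-field style); a
uniform reference is the identity. Pixel ranges (`"unit"` [0,1] or `"byte"`
[0,255]) are carried explicitly so the linear map onto the network's
[−1, 1] input/output space — and its exact inverse — is never ambiguous.

## 2. The wavelet EDoF baseline and training targets

Classical multi-scale-decomposition fusion supplies both the comparison
baseline and the training targets (computed from *fully sampled* stacks).
Each plane's luminance is decomposed with a periodized separable orthogonal
DWT; for every detail coefficient the plane maximising a sharpness
criterion wins; the fused pyramid is inverted.

Defaults (`wavelet_fusion_config()`):

* **sym4** filters — near-symmetric orthogonal, 4 vanishing moments; haar,
  db2, db4 are available. Orthogonality plus periodization gives perfect
  reconstruction at machine precision (tested to < 1e-8), and images are
  symmetrically padded to multiples of `2^levels` and cropped back.
* **levels = 4**: finest four dyadic scales cover the size range of cell
  and parasite detail at ~0.1 µm/px sampling.
* **selection = max_local_energy** (3×3 window of squared coefficients),
  more noise-robust than a pointwise |coefficient| rule; ties go to the
  lower plane index (deterministic).
* **consistency_radius = 1**: a majority filter over each selection map
  suppresses isolated mis-selections; exact ties keep the original label.
* **luminance_guided** colour handling: selection maps are computed once on
  Rec.709 luminance and applied identically to all three channels, so
  colour never fringes at selection boundaries. The coarsest approximation
  band is averaged across planes.

Published EDoF pipelines of this kind often rely on complex B-spline
wavelet implementations whose internals are not documented in enough detail
to replicate; the configuration above is a fully specified, reproducible
representative of the method class, and the filter family is pluggable.

## 3. The fusion network

`cami_fuse()` implements `O = tanh(C(max(R(E(I_1)), …, R(E(I_D)))))`: a
shared stride-2 convolutional encoder `E` (NL stages, channels
3 → Ed/2 → … → Ed, kernel 3, leaky-ReLU 0.2, no normalisation layers), five
residual blocks `R` (conv → leaky-ReLU → conv, additive skip), element-wise
max over the D plane features, and a transposed-convolution decoder `C`
back to H×W×3 with a tanh output. Because the weights are shared across
planes and max is commutative and associative, the output is *exactly*
invariant to plane order and the parameter count is independent of D: the
same trained model fuses 3, 7 or 14 planes.

Design choices where the architecture was open:

* **Decoder kernel 4** (`up_kernel_size`): stride-2 transposed convolutions
  with odd kernels overlap unevenly (alternate output pixels receive
  different numbers of taps), which imprinted a visible checkerboard on
  otherwise flat backgrounds in pilot runs; an even 4×4 kernel overlaps
  uniformly and removed the artifact. Encoder/residual convolutions stay
  3×3.
* **Residual branch zero-init**: the second convolution of every residual
  block starts at zero, so each block is the identity at initialisation.
  With generic He initialisation the five-block chain amplified feature
  magnitudes ~10× and partially saturated the tanh output before training
  began; with some seeds the optimiser never escaped that regime. Zero-init
  removes the seed lottery; the first convolution keeps He init.
* **No normalisation layers, no input skip**: the composition above is the
  whole forward pass.

The implementation is plain R: feature maps are (H·W)×C matrices, convolved
via cached im2col index gathers feeding BLAS multiplies; transposed
convolutions are the exact adjoints of the corresponding stride-2
convolutions; gradients are hand-derived and validated against central
finite differences in the test suite. Training is fully deterministic given
the config seed.

## 4. The loss

`l = λ1·lMAE + λ2·lSSIM + λ3·lFFT`, weights 1.0 / 0.1 / 0.5, computed in
the [−1, 1] space (targets mapped like the inputs; SSIM dynamic range 2):

* `lMAE`: mean |output − target| over pixels and channels;
* `lSSIM = 1 − SSIM`, so the component is non-negative and 0 at optimum;
* `lFFT`: mean modulus of the *complex difference* of the 2-D DFTs, per
  channel. Taking the modulus after differencing (rather than differencing
  moduli) penalises phase errors too and vanishes iff the images are equal.

All three components and the combined gradient are checked against
independent brute-force oracles (direct summation, direct windowed SSIM,
explicit DFT-matrix evaluation, finite differences).

## 5. Metrics

* **SSIM**: 11×11 Gaussian windows (σ = 1.5), `C1 = (0.01 L)²`,
  `C2 = (0.03 L)²` — the original reference defaults; only fully interior
  windows contribute; RGB is reduced to Rec.709 luminance.
* **Pearson correlation** over flattened luminance values.
* **HaarPSI**: local similarity of the first two Haar wavelet scales in two
  orientations, logistic constant C = 30 and sharpening exponent α = 4.2
  (the defining reference's values on the [0, 255] scale), weighted by the
  third-scale magnitude; RGB inputs contribute a chroma (YIQ) similarity
  term. Unit-range inputs are rescaled internally.

All three metrics accept grayscale matrices directly; for RGB input,
luminance is the default reduction for SSIM and CORR, while HaarPSI keeps
its chroma terms.

## 6. The synthetic blood-film simulator

`generate_scene()` + `render_stack()` emulate a thin stained film: sparse
erythrocytes (pale annuli with central pallor, radius 3.5–4 µm), small
dark-violet ring parasites (1–1.5 µm), textured lobed leukocytes, dark dust
specks, each at a uniform random depth within the slab. Defaults:

* slab thickness 3 µm, 7 planes at 0.5 µm (thin-smear regime); the
  thick-film preset uses 14 planes over 6.5 µm;
* field 128 px at 0.13 µm/px (a 2×2-binned high-NA camera: keeps a whole
  erythrocyte inside a 64-px training patch while preserving the
  object-to-PSF size ratio);
* defocus PSF `σ(dz) = 0.8 + 1.5·|dz|` px — a Gaussian stand-in producing
  the sharp-at-focus / blurred-away structure fusion exploits, not a
  physical Airy/defocus kernel;
* additive Gaussian noise, σ = 0.01 of full scale.

What the simulator does **not** model: Poisson shot noise, chromatic or
field aberrations, stain variability, overlapping semi-transparent cells,
stage jitter. Tests passing on simulated stacks therefore demonstrate the
pipeline's mechanics and the learning effect, not clinical performance.

One measured interaction is worth recording: with sensor noise enabled, the
max-energy coefficient selection also concentrates *noise* from across the
stack into the fused image, so on nearly-flat fields the wavelet EDoF of a
full noisy stack need not beat the sharpest single plane in SSIM, even
though it always does on noise-free renders. The focus-fusion property is
accordingly tested at `noise_sigma = 0`, while every training and
comparison experiment keeps the noisy default — where the network's
implicit denoising is part of what it learns.

## 7. Scaled-down experiment sizes

The package's end-to-end experiment (test suite and `scripts/acceptance.R`)
uses 50 simulated stacks (40 train / 10 held out), inputs decimated by
k = 2 to three planes, and the small configuration
`small_net_config()`: NL = 2, Ed = 16, five residual blocks, 64-px patches,
batch 2, 500 Adam steps. These sizes keep a full run in the minutes range
on one CPU while preserving the structure of the full-scale setup (159/30
stacks, 256-px patches, learning rate 1e-4), which remains the default of
`fusion_net_config()`.

The small schedule uses **learning rate 4e-3**: a ~30k-parameter model
updated only 500 times needs a larger step than the long full-scale
schedule; 1e-3–4e-3 all converged in pilot runs and 4e-3 converged
furthest. This choice was frozen before the evaluation experiments and is
not adapted per run.

## 8. Degenerate inputs, ties, tolerances

* One-plane stacks are valid everywhere (fusion degenerates to the plane;
  the network runs as an autoencoder).
* Coefficient-selection and max-fusion ties resolve to the lowest plane
  index; majority-filter ties keep the original label.
* Constant images make Pearson correlation undefined: `NA` with a warning.
* A white reference with near-zero pixels is clamped to ε with a warning.
* Reconstruction tolerances: DWT round trip < 1e-8 (machine precision in
  practice); [−1, 1] normalisation inverts to < 1e-6; fusion of D identical
  planes returns the plane to < 1e-6.

## 9. Known limitations

* The wavelet baseline is a faithful *class* representative of MSD fusion,
  not a numerical replica of any specific published implementation.
* The network trains on a CPU at desk scale; no GPU path, no mixed
  precision, no multi-scale fusion variants.
* HaarPSI is validated by construction properties (identity, bounds,
  symmetry, monotone degradation), not against an external implementation.
* Simulated scenes are sparse and opaque; crowded thick-film fields with
  overlapping cells are outside the generator's fidelity.
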