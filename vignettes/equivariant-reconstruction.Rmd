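---
title: "Equivariant learned reconstruction: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivariant learned reconstruction: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`steerrec` builds learned iterative reconstruction methods for tomographic
inverse problems out of roto-translationally equivariant convolutional
blocks. This vignette is the package's own account of the underlying models,
the tunable parameters, and the numerical decisions taken where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The reconstruction problem

We estimate an image $u$ from noisy indirect measurements $y = \mathfrak{N}(A u)$,
where $A$ is a known linear forward operator. Two simulated modalities are
provided:

* **Low-dose CT.** $A = \mathcal{R}$ is a parallel-beam ray transform with 50
  uniformly spaced views in $[0, \pi)$. Measurements are post-log photon
  counts: $n \sim \mathrm{Pois}(N_{\mathrm{in}} e^{-\mu \mathcal{R} u})$ and
  $y = -\tfrac{1}{\mu}\log\max(n / N_{\mathrm{in}}, \eta)$ with
  $N_{\mathrm{in}} = 10^4$ photons per detector pixel and $\eta = 10^{-8}$.
* **Subsampled MRI.** $A = \mathcal{S}\mathcal{F}$ is a unitary 2-D discrete
  Fourier transform followed by variable-density Cartesian line masking;
  complex white Gaussian noise is added on the sampled lines. Complex images
  travel through the networks as two real channels.

Both use the quadratic discrepancy $E_y(u) = \tfrac12\|A u - y\|^2$, whose
gradient $A^\top(Au - y)$ is evaluated with the *exact* adjoint of the
discretised forward operator.

## Classical backbone: proximal gradient splitting

For a penalty $J$, the proximal gradient method iterates
$u \leftarrow \mathrm{prox}_{\tau J}(u - \tau \nabla E_y(u))$ with
$\mathrm{prox}_J(u) = \arg\min_v \tfrac12\|u - v\|^2 + J(v)$. Two classical
penalties are built in: the Tikhonov squared norm, whose prox is the exact
shrinkage $u / (1 + \tau\lambda)$, and isotropic total variation, whose prox
is computed by projected gradient ascent on the dual with the classical
fixed step $1/8$ (in the scaled dual variables) and a duality-gap stopping
rule (default $10^{-8}$ relative).

A key structural fact drives the whole package: if $J$ is invariant under a
unitary group action, its proximal operator *commutes* with that action.
`check_prox_equivariance()` verifies this numerically: exactly for the
Tikhonov prox, and for TV up to solver tolerance — but only if the discrete
functional itself is invariant. The default forward-difference TV stencil is
*not* exactly invariant under quarter-turn rotations, so the package also
provides a symmetrised variant (the mean of the functional over the four
quarter-turn rotations of its argument), which is exactly invariant, making
the theorem testable at the discrete level. The symmetrised prox is solved
with one dual field per rotated stencil.

The full variational solution map $u \mapsto \hat u(A u)$ is nevertheless
**not** equivariant when measurements are incomplete — information enters
and leaves the sampled region as the image rotates. The test suite
reproduces this directionally for a masked-Fourier operator.

## Steerable convolutions

A convolution with matrix-valued kernel $k$ between feature fields that
transform under representations $\pi_{\mathrm{in}}, \pi_{\mathrm{out}}$ of a
rotation group is equivariant precisely when
$k(Rx) = \pi_{\mathrm{out}}(R)\, k(x)\, \pi_{\mathrm{in}}(R^{-1})$.
For the finite cyclic groups $\mathbf{Z}_m$ used here, with trivial and
regular representations only, the package solves this constraint *directly*:
the constraint for the group generator is assembled as a linear map on the
vectorised $s \times s$ kernel and its null space is computed by singular
value decomposition (relative singular values below $10^{-10}$ kept). For a
cyclic group the generator constraint implies the constraint for every
element. This replaces the general irreducible-representation route (with
change-of-basis matrices) used by steerable-CNN software for arbitrary
compact groups: for our representations the direct solve is exact, small,
and easy to cross-check against orbit counting — for scalar kernels the
basis dimension equals the number of group orbits on the grid cells
(9, 5, 3 for $m = 1, 2, 4$ on a $3\times3$ kernel).

Numerical conventions that matter:

* **On-grid vs off-grid groups.** For $m \in \{1, 2, 4\}$ the spatial
  rotation of the kernel grid (and of images) is an exact array
  permutation, so equivariance claims are exact and tested at tight
  tolerances. For other $m$ the grid rotation uses bilinear resampling with
  zero fill and all equivariance is approximate; such results carry an
  `approximate` flag.
* **Bias tying.** One bias per output field, replicated across the field's
  channels. Under a channel-permuting regular representation an untied bias
  would break equivariance.
* **Padding.** Default zero padding. Zero padding preserves *rotation*
  equivariance about the image centre exactly (the zero boundary is
  rotation-symmetric) but breaks translation equivariance at the boundary;
  the equivariance test harness therefore uses circular padding, under
  which integer roto-translations commute with the layers to machine
  precision (asserted at $10^{-5}$, observed near $10^{-15}$).
* **Initialisation.** He-style fan-in scaling, transported to the steerable
  parameterisation: coefficients are drawn i.i.d. normal with variance
  chosen so the expanded kernel matches the per-element He variance
  $2/(s^2 C_{\mathrm{in}})$ (the basis is Frobenius-orthonormal, so the
  coefficient-to-kernel map is an isometry per block).

Pointwise nonlinearities (the leaky ReLU $\phi(x) = x$ for $x > 0$, else
$0.01x$) are equivariant exactly when every field type acts by permutation
matrices — trivial or regular representations; the package enforces this
precondition. A norm nonlinearity $f \mapsto f\,\phi(\|f\|)$ is provided for
general unitary types.

## The unrolled learned method

The learned proximal gradient method runs, from $u^0 = 0$ and memory
$s^0 = 0$,
$$(u, s) \leftarrow \widehat{\mathrm{prox}}_i(u, s, \nabla E_y(u)),
\qquad i = 1, \dots, \mathrm{it},$$
and returns the final $u$. Each $\widehat{\mathrm{prox}}_i$ is the
three-affine-layer block
$K_{\mathrm{project}} \circ (\mathrm{id} + \phi \circ K_{\mathrm{intermediate}}) \circ K_{\mathrm{lift}}$,
read literally: exactly three convolutions, one nonlinearity, one residual
branch, untied across iterations. $K_{\mathrm{intermediate}}$ (weights and
bias) starts at zero, so at initialisation the block is exactly
$K_{\mathrm{project}} \circ K_{\mathrm{lift}}$ — an analytically checkable
state. Channel accounting for CT: lift input $7 = 1 + 5 + 1$ (image, memory,
gradient), project output $6 = 1 + 5$; for MRI $9 = 2 + 5 + 2$ and
$7 = 2 + 5$. The memory state is five scalar channels, initialised to zero
per reconstruction and not penalised.

The **equivariant flavour** lifts trivial input fields to
$\mathrm{width}/m$ regular fields and projects back; the **ordinary
flavour** uses unconstrained convolutions with identical channel counts, so
activation shapes match layer-by-layer and the ordinary parameter space
strictly contains the equivariant one. `subsumption_embed()` makes that
concrete by expanding a trained equivariant net into ordinary weights whose
outputs agree to machine precision. Replacing every
$\widehat{\mathrm{prox}}_i$ by the classical update
$\mathrm{prox}_{\tau J}(u - \tau g)$ recovers the classical splitting method
exactly, which the tests assert.

The end-to-end reconstruction map is *not* claimed equivariant: the
discrepancy gradient is generally not an equivariant operator. Only each
prox-net is, and that is what the harness asserts. (For the specific CT
geometry used here — 50 angles, odd detector count — quarter-turn rotations
happen to commute with $A^\top A$ as well, which is why rotation robustness
of the whole equivariant pipeline is observed in the experiments.)

### Training

Empirical risk minimisation of the mean squared reconstruction error with
Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), minibatch
size 1, deterministic given the seed. Gradients are computed by exact
backpropagation through the unrolled iterations, including the
$A^\top A$ term that the gradient input contributes at every iteration, and
— for the equivariant flavour — through the basis expansion (the gradient of
a kernel is projected onto the steerable basis; tied biases accumulate their
channels' gradients). The per-sample loss is the *mean* over pixels rather
than the sum, so learning rates transfer across image sizes.

Two presets coexist:

* **Reference preset** (the scale the method is normally run at on GPU
  hardware): depth $\mathrm{it} = 8$, intermediate width 96, $m = 4$,
  learning rate $10^{-4}$, $10^5$ Adam iterations.
* **Desk-scale preset** (what the experiments in this package actually run,
  chosen to finish on a single CPU): $64\times64$ phantoms,
  $\mathrm{it} = 2$, width 12, learning rate $10^{-3}$, 600 Adam
  iterations with Adam warm restarts (moment reset every 150 iterations,
  applied identically to both flavours), ray-integration step 1 pixel,
  medians over 3 seeds. The schedule length matters scientifically: per Adam step the equivariant
  flavour moves less in kernel space (it has a quarter of the
  coefficients of the width-matched ordinary net, and Adam steps each
  coordinate at the learning rate), so it needs roughly twice the
  schedule to reach its plateau; short schedules systematically favour
  the ordinary flavour. 600 iterations is past the convergence knee of
  both flavours at this width and depth.

One further conditioning choice makes short schedules workable: the forward
operator handed to a network is normalised to unit operator norm
(`op_normalise()`, power-iteration estimate; measurements scaled to match).
Without it the raw Radon $\|A^\top A\|$ is of order $10^3$–$10^4$ and a short
Adam run spends its whole budget learning a scale factor. This rescaling
changes nothing about the underlying problem.

## Synthetic data

The generators replace clinical datasets at desk scale and define the study
conditions:

* `ellipse_phantom()` overlays randomly placed, **deliberately elongated**
  ellipses (axis ratios 0.2–0.55) with ~1-pixel anti-aliased edges, clipped
  to the declared intensity range. By default the ellipses share a
  preferred orientation ($\pi/5$ with $\pm\pi/12$ jitter), emulating the
  consistent patient orientation of clinical scans. Both choices are
  deliberate: isotropic blobs, or fully random orientations, would make the
  image *distribution* rotation-invariant, in which case rotated test
  images are not out-of-distribution and no rotation-robustness gap between
  ordinary and equivariant methods could exist in principle. Pass
  `orientation = NA` for rotation-invariant phantom statistics.
* `figure1_fixture()` builds the single-pair denoising task: parallel
  oblique bars (orientation $\pi/7$) plus additive Gaussian noise of
  standard deviation 0.3, with 90°-rotated test copies. The default test
  rotation is the exact quarter turn so that rotation itself introduces no
  interpolation loss; a 20° option exists to demonstrate that off-grid
  rotation smooths high-frequency content (bilinear interpolation strictly
  decreases the total variation of a checkerboard, which a test asserts).
* `make_dataset()` derives disjoint per-pair seeds from one master seed;
  every generator is a pure function of its seed (byte-identical reruns).

What these phantoms do **not** emulate: anatomical texture, scanner
physics beyond Poisson counting statistics (no scatter, beam hardening,
coil sensitivities), and realistic object scale. Passing tests therefore
demonstrate the *mechanism* — constraint satisfaction, equivariance,
subsumption, and the direction of the small-training-set effect — not
clinical performance.

## Experiment design choices

* **Single-pair denoising comparison** (`figure1_experiment()`): the
  "single-layer denoiser" is one prox-net block (lift, leaky ReLU,
  project; a literal single linear filter cannot denoise), width-matched
  between flavours, trained 400 Adam iterations at learning rate $10^{-3}$
  on one clean/noisy pair, identity forward operator. Reported: upright and
  rotated PSNR per flavour, medians over 3 seeds.
* **Small-training-set comparison** (`small_training_comparison()`): CT on
  $64\times64$ phantoms, $N = 20$ training pairs, the desk-scale preset
  above, held-out phantoms evaluated upright and rotated by random quarter
  turns with measurements re-simulated from the rotated truth (no
  interpolation confound). The comparison statistic is the median
  rotated-test PSNR of each flavour.

## Metrics

PSNR uses the printed definition with the peak taken from the ground truth
($n \max_i |u_i|^2 / \|u - \hat u\|^2$, in dB), returning an `Inf` sentinel
for identical inputs rather than raising. SSIM uses a uniform $7\times7$
window, population window statistics, and stabilisers $(0.01L)^2$,
$(0.03L)^2$ with $L$ the ground truth's data range; the masked variant
reflection-pads by $\lfloor w/2 \rfloor$ so that the SSIM map is
pixel-aligned, then averages over the mask (the full mask reproduces the
padded global SSIM exactly). Complex images are evaluated on their
magnitudes. Whether to clip CT images to a display window before computing
metrics is left to the caller; the package computes metrics on raw values.

## Known limitations

* Only cyclic rotation groups with trivial/regular representations;
  no reflections, no continuous-group irreducible representations,
  kernel grids square and odd.
* Exactness claims are restricted to on-grid groups ($m \mid 4$); for other
  orders both the basis and the image action rely on bilinear resampling.
* The Radon adjoint is the exact transpose of the *discretised* forward map
  (which is what the gradients need), not a high-order quadrature of the
  continuous adjoint.
* Training is plain Adam in R with compiled inner loops; it is adequate for
  the desk-scale presets, not for reference-scale runs.
* FBP with the band-limited ramp reconstructs smooth phantoms to a few
  percent; discontinuous phantoms are edge-limited at this resolution
  (the test uses a smooth-edged disk for exactly this reason).
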