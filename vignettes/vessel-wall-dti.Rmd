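---
title: "Methods: estimating 2D diffusion tensors in the arterial wall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating 2D diffusion tensors in the arterial wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwdti)
```

## The measurement model

The arterial wall's collagen and smooth-muscle architecture is
predominantly circumferential. In an imaging slice perpendicular to the
vessel's long axis, water therefore diffuses faster along the wall tangent
than radially, and through-plane (longitudinal) diffusion is small. This
motivates reducing the usual 3D diffusion tensor to a 2×2 in-plane tensor,
sampled with gradient directions on a **hemicycle** — half a circle, since
opposite gradients produce identical diffusion weighting.

Per direction $g=(g_x,g_y)$, the signal follows the mono-exponential decay
$S(b)=S_0 e^{-bD}$ with $D = g^\top \mathbf{D} g$. Stacking the fitted
per-direction coefficients into $Y$ gives the linear system $Y = H d$ with
$H_i = [g_{x,i}^2,\; g_{y,i}^2,\; 2 g_{x,i} g_{y,i}]$ and
$d = [D_{xx}, D_{yy}, D_{xy}]^\top$, solved per voxel by least squares.
Eigendecomposition yields the tangential ($\lambda_1$) and radial
($\lambda_2$) diffusivities and the scalar maps
$\mathrm{FA} = (\lambda_1-\lambda_2)/\sqrt{\lambda_1^2+\lambda_2^2}$,
$\mathrm{MD} = (\lambda_1+\lambda_2)/2$, $\mathrm{RD} = \lambda_2$.

Assumptions worth keeping in mind:

* **Mono-exponentiality.** A single $D$ per direction ignores perfusion
  (IVIM) and kurtosis effects; at $b \le 600\ \mathrm{s/mm^2}$ in wall
  tissue this is the standard operating regime.
* **In-plane reduction.** The 2D tensor is blind to the longitudinal
  eigenvalue. When longitudinal diffusion is genuinely small the in-plane
  eigenvalues match their 3D counterparts (this is a tested property, see
  below), but 2D FA is systematically higher than 3D FA because the third
  eigenvalue is absent from the formula.
* **Registered input.** The package expects motion-corrected, registered
  stacks; registration itself is out of scope.

## Gradient scheme

`make_hemicycle_scheme(n)` places $n$ unit directions at evenly spaced
angles $\theta_k = k\pi/n$. Even spacing is the natural choice in the
absence of a stated optimum: it maximises angular coverage and conditions
$H$ well — for $n=18$ the design-matrix condition number is ≈1.41 (the
test suite checks it is below 10). Three distinct angles are the
identifiability minimum; 18 matches the acquisition this package targets
(10° spacing).

Directions are lifted into the scanner frame by a deterministic
Gram–Schmidt basis anchored on the x-axis (y-axis fallback when the plane
normal is parallel to x), so written `bvec` files are reproducible
bit-for-bit. The signed elevation angle
$\theta = \pi/2 - \arccos(z/\lVert v\rVert)$ (degrees, negative below the
plane) summarises how far any fitted principal direction tilts out of
plane; the signed convention keeps distributions of near-in-plane
directions centred at 0 rather than folded.

## Per-direction ADC fitting

`fit_monoexp` minimises $\sum_i (S_i - S_0 e^{-b_i D})^2$ by damped
(Levenberg–Marquardt) least squares, vectorised across voxels: the
$2\times2$ normal equations have a closed-form solution, so one iteration
is a handful of elementwise array operations regardless of voxel count.
Numerical choices:

* **Initialisation** from the log-linear fit of $\ln S$ on $b$, weighted
  by $S^2$ (first-order propagation of additive noise through the log).
  On noiseless data this initialisation is already exact.
* **Bounds** $D \in [0, 0.02]\ \mathrm{mm^2/s}$ — an order of magnitude
  above free water; boundary hits are flagged per voxel, and negative
  decays clamp to 0 with a flag.
* **Convergence**: relative cost change below $10^{-10}$, cap 200
  iterations; per-voxel damping $\lambda$ shrinks ×3 on accepted steps and
  grows ×4 on rejected ones.
* Each direction is fitted independently with its own $S_0$; the $b=0$
  measurements are shared across directions as data. Voxels whose $b=0$
  signal falls below a configurable `noise_floor` are excluded and flagged.

## Tensor solve and eigen-analysis

The overdetermined solve uses pivoted (rank-revealing) QR; the explicit
normal-equations form $(H^\top H)^{-1} H^\top Y$ exists only as a test
oracle. The 2×2 eigendecomposition is closed-form; of the two equivalent
eigenvector expressions the numerically larger is used, degenerate
isotropic tensors return $\varepsilon_1 = (1,0)$ by convention, and signs
are fixed so the first nonzero component is nonnegative — all of which
makes vector-map files reproducible. Noise can push $\lambda_2$ (rarely
$\lambda_1$) negative; eigenvalues are clamped to 0 for the scalar maps
and the voxel flagged, and flagged voxels are excluded from ROI means.
Reported ROI FA is the mean of voxelwise FA (mean of ratios), not the FA
of mean eigenvalues; the two differ and the former matches how
per-subject summaries are conventionally tabulated.

The reference 3D pipeline (`tensor_pipeline_3d`) reports sorted
eigenvalues plus each eigenvector's elevation angle to the plane. It
deliberately does not label $\lambda_2$ versus $\lambda_3$ anatomically:
when radial and longitudinal diffusivities are comparable the assignment
is ambiguous, and the angle maps carry the information instead.

## Two-pool analysis and b-value choice

Wall ADC histograms show two populations. `fit_adc_pools` fits a
two-component Gaussian mixture by EM with a deterministic initialisation
(split at the median), a variance floor to survive degenerate point-mass
inputs, and a $10^{-10}$ relative log-likelihood tolerance (cap 500
iterations). The deterministic start makes results reproducible without a
seed; tests verify it attains the likelihood of 50 random restarts and
agrees with an independent mixture implementation.

The b-value maximising the signal difference between two pools,
$\arg\max_b S_0(e^{-bD_{slow}} - e^{-bD_{fast}})$, has the closed form
$\ln(D_{fast}/D_{slow})/(D_{fast}-D_{slow})$, independent of $S_0$ and
symmetric in the pool labels, with limit $1/D$ as the coefficients
coalesce. For pool means $2.11\times10^{-3}$ and $1.27\times10^{-3}\
\mathrm{mm^2/s}$ this gives $604.4 \approx 605\ \mathrm{s/mm^2}$,
supporting $b = \{0,200,400,600\}$ as an equidistant set spanning zero to
the maximum-contrast weighting.

## The synthetic phantom: what it does and does not emulate

`make_phantom` builds an annulus with the analytic wall tensor
$\mathbf{D} = \lambda_t\, t t^\top + \lambda_r\, r r^\top$ ($t$ tangent,
$r$ radial at each voxel's polar angle), isotropic lumen and background
compartments, and magnitude (Rician) noise
$\sqrt{(S+n_1)^2 + n_2^2}$ with $\sigma = S_{0,wall}/\mathrm{SNR}$.
Defaults mirror the targeted carotid protocol: 128×128 at 0.55 mm,
$b = 0/200/400/600\ \mathrm{s/mm^2}$, 18 directions, SNR 30,
$\lambda_t = 1.6\times10^{-3}$, $\lambda_r = 0.5\times10^{-3}\
\mathrm{mm^2/s}$ (within the range observed in vivo), a 3 mm lumen
radius with a 1.2 mm wall, and a flow-suppressed (low-signal) lumen.

The phantom emulates: tangential-dominant anisotropy, Rician floor
effects (ADC underestimation at low SNR — a tested directional property),
scan–rescan variability via independent noise realisations, and arbitrary
in-plane rotations (the annulus is rotation-symmetric, which the
invariance tests exploit). It does **not** emulate partial volume at the
wall boundaries (hard masks keep ground truth exact), the 10 mm slice
profile, pulsatile motion, eddy currents, or registration error.
Consequently, passing phantom tests demonstrates correctness of the
estimation chain, not in vivo accuracy: phantom scan–rescan CV at SNR 30
is ~0.3–0.5 %, an order of magnitude below in vivo repeatability, because
physiological variability is absent.

Validation problem sizes, chosen to exercise every property at
comfortable statistical resolution: noiseless round trips and rotation
invariance on a 48-px carotid-geometry annulus (~90 wall voxels); the
SNR-30 recovery checks on a 128-px aorta-like ring (~590 wall voxels,
echoing the ex vivo validation vessel); repeatability-versus-SNR on a
32-px ring (~170 voxels) with five replicate sets of four repeats at SNR
10/30/100.

## Zero-filling interpolation

`zero_fill_interpolate` upsamples by symmetric zero-padding of the FFT
spectrum: DC-centred embedding, the Nyquist row/column of even-sized
sources split half-and-half between ±Nyquist (keeping the padded spectrum
Hermitian so the inverse transform is real up to rounding), inverse FFT,
magnitude, and scaling that preserves the image mean. It reproduces the
source exactly at coarse-grid positions and matches direct evaluation of
the periodic Fourier series (tested at $10^{-8}$). Note two properties of
this construction: interpolation happens on the periodic grid (so the
rotation it commutes with is rotation about the DFT origin), and applying
it to magnitude DWI data correlates noise between neighbouring pixels —
it is therefore optional and off by default in the fitting pipeline.

## Statistics

`roi_summary` uses the sample (n−1) standard deviation — this reproduces
published repeatability σ columns at printed precision — and percent CV
$= 100\,\sigma/\bar{x}$, flagged undefined at zero mean. CV checks in the
acceptance tests carry a ±0.15 percentage-point tolerance because printed
table values are rounded to three decimals before the CV is formed.
`ols_fit` wraps ordinary least squares with the single-predictor F test
(identical to the squared-t test, verified to $10^{-12}$) and t-quantile
95 % confidence and prediction bands. Adjusted $R^2$ follows
$1-(1-R^2)(n-1)/(n-2)$ and may be negative — as it indeed is for the
primary-eigenvalue-versus-age relation in the bundled volunteer table.

## Known limitations

* Single slice by design; no multi-slice or volumetric support.
* No IVIM/kurtosis modelling; $T_2$ decay enters only through $S_0$.
* The two-stage estimator (per-direction ADC, then linear solve) is not a
  maximum-likelihood tensor fit under Rician noise; at SNR ≥ 10 the
  residual bias is small (tested), but very-low-SNR data will be biased
  low.
* ROI statistics treat voxels as independent; zero-fill interpolation
  (if applied) violates this, which is one reason it defaults to off.
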