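# vwdti — two-dimensional diffusion tensor imaging of the vessel wall

`vwdti` quantifies in-plane diffusion anisotropy of the arterial wall from
single-slice, high-resolution diffusion-weighted MRI. The arterial media is
organised circumferentially, so in a slice perpendicular to the vessel's
long axis water diffuses preferentially along the wall's tangent. Sampling
diffusion-encoding gradients on an in-plane **hemicycle** (18 directions
spanning half a circle) makes a 2×2 in-plane tensor identifiable with far
fewer measurements than a conventional 3D scheme — short enough for clinical
carotid imaging. The package is aimed at quantitative-MRI researchers who
want to estimate, validate and analyse such 2D tensor data.

## Model

For each gradient direction *g* = (g_x, g_y) the signal decays
mono-exponentially with the b-value,

    S(b) = S0 · exp(−b·D),

and the per-direction apparent diffusion coefficients *Y* relate linearly to
the unique tensor elements **d** = [D_xx, D_yy, D_xy]ᵀ through

    Y = H d,    H_i = [g_x,i²,  g_y,i²,  2·g_x,i·g_y,i].

With n ≥ 3 distinct hemicycle angles the system is (over)determined and
solved by least squares per voxel. Eigendecomposition of the 2×2 tensor
yields λ₁ ≥ λ₂ (tangential and radial diffusivity), and

    FA = (λ₁ − λ₂) / √(λ₁² + λ₂²),   MD = (λ₁ + λ₂)/2,   RD = λ₂.

Supporting tools: a two-pool Gaussian-mixture analysis of ADC histograms
with the closed-form optimal b-value `ln(D_fast/D_slow)/(D_fast − D_slow)`;
a synthetic annular phantom with analytic tangential tensors and Rician
noise; zero-filling (Fourier) interpolation; ROI/repeatability statistics
(mean, σ, CV) and age-regression with 95 % confidence/prediction bands; a
reference 3D tensor pipeline for validating the 2D reduction.

## Worked example

Simulate a noisy annular vessel phantom, fit the 2D tensor, and compare
against ground truth:

```r
library(vwdti)
cfg <- phantom_config(n_pixels = 64L, r_lumen = 5, r_outer = 8,
                      snr = 30, seed = 42)
ph  <- make_phantom(cfg)                       # 400 wall voxels
fit <- tensor_pipeline_2d(ph$stack, cfg$scheme, mask = ph$truth$wall_mask)
ok  <- fit$flags == 0L
mean(fit$maps$FA[ok])   # 0.656  (analytic truth: fa_2d(1.6e-3, 5e-4) = 0.656)
mean(fit$maps$MD[ok])   # 1.05e-3 mm^2/s (truth (1.6e-3 + 5e-4)/2 = 1.05e-3)
```

Analyse the bundled per-volunteer summary table (mean wall FA of 12
healthy men, ages 27–57) and the repeated-measurement table:

```r
tab <- read.delim(vwdti_example("carotid_dti_volunteers.tsv"))
ols_fit(tab$age, tab$fa)
#> Linear regression (n = 12): y = -0.004864x + 0.7856
#>   R^2 = 0.566 (adjusted 0.523), F = 13.042, p = 0.004757

optimal_bvalue(2.11e-3, 1.27e-3)   # 604.37 s/mm^2 -> b ~ 605 is optimal

rep <- read.delim(vwdti_example("fa_repeatability.tsv"))
roi_summary(rep$R3)
#> ROI summary (n = 4): mean = 0.6078, sd = 0.01497, CV = 2.46%
```

FA falls by ~0.005 per year of age in this cohort (p < 0.01, adjusted
R² 0.52), while scan–rescan CV of mean FA is a few percent — anisotropy is
both age-sensitive and reproducibly measurable.

The same workflow is available from the shell via the bundled CLI
(`inst/cli/vwdti`): `simulate`, `fit`, `optimal-b`, `repro` and `regress`
subcommands, each writing a provenance JSON alongside its outputs.

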