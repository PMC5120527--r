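Package: vwdti
Title: Two-Dimensional Diffusion Tensor Imaging of the Vessel Wall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying in-plane diffusion anisotropy in the
    arterial vessel wall from high-resolution diffusion-weighted MRI.
    Builds hemicycle gradient-direction schemes perpendicular to the
    vessel's long axis, fits a mono-exponential decay per diffusion
    direction to obtain apparent diffusion coefficients, estimates the
    two-dimensional (and reference three-dimensional) diffusion tensor by
    least squares, and derives eigenvalue, fractional anisotropy, mean
    diffusivity and radial diffusivity maps. Includes a two-pool ADC
    mixture analysis with closed-form optimal b-value selection, a
    synthetic annular vessel-wall phantom with Rician noise for
    validation, region-of-interest repeatability statistics, and
    age-regression analysis with confidence and prediction bands.
    Reads and writes NIfTI images with FSL-style bval/bvec tables and
    ships a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    mclust
Config/testthat/edition: 3
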