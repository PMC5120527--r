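#' Configuration for the annular vessel-wall phantom
#'
#' Assembles and validates the parameters of the synthetic single-slice
#' vessel phantom: an annular wall around a circular lumen, with a
#' tangential-dominant diffusion tensor at every wall voxel (principal
#' eigenvector along the circumference, minor eigenvector radial) and
#' isotropic diffusion elsewhere. Defaults mirror a high-resolution
#' carotid protocol: 128 x 128 matrix at 0.55 mm, b = 0/200/400/600
#' s/mm^2, 18 hemicycle directions, and wall diffusivities in the range
#' observed in vivo.
#'
#' @param n_pixels Image size (square), default 128.
#' @param spacing Pixel spacing in mm, default 0.55.
#' @param center Vessel centre in pixel coordinates (default image
#'   centre).
#' @param r_lumen,r_outer Lumen and outer wall radii in mm (defaults 3
#'   and 4.2: a ~6 mm lumen with a ~1.2 mm wall).
#' @param lambda_t,lambda_r Tangential and radial wall diffusivities in
#'   mm^2/s (defaults 1.6e-3 and 0.5e-3).
#' @param lambda_l Longitudinal (through-plane) wall diffusivity, used
#'   only when simulating 3D direction sets (default 0: negligible
#'   diffusion along the vessel axis).
#' @param d_lumen Isotropic lumen diffusivity (default 3.0e-3, blood).
#' @param d_background Isotropic background diffusivity (default 0.8e-3).
#' @param S0_wall,S0_lumen,S0_background Unweighted signal levels
#'   (defaults 100, 10, 5; the low lumen signal mimics flow suppression).
#' @param bvals b-values in s/mm^2 including 0 (default 0, 200, 400, 600).
#' @param scheme In-plane `gradient_scheme` (default 18 hemicycle
#'   directions).
#' @param snr Signal-to-noise ratio `S0_wall / sigma`; `Inf` disables
#'   noise (default 30).
#' @param seed Integer seed for the noise generator (default 1).
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(n_pixels = 128L, spacing = 0.55,
                           center = NULL, r_lumen = 3, r_outer = 4.2,
                           lambda_t = 1.6e-3, lambda_r = 0.5e-3,
                           lambda_l = 0, d_lumen = 3.0e-3,
                           d_background = 0.8e-3,
                           S0_wall = 100, S0_lumen = 10, S0_background = 5,
                           bvals = c(0, 200, 400, 600),
                           scheme = make_hemicycle_scheme(18L),
                           snr = 30, seed = 1L) {
  if (is.null(center)) center <- rep((n_pixels + 1) / 2, 2L)
  cfg <- list(n_pixels = as.integer(n_pixels), spacing = spacing,
              center = center, r_lumen = r_lumen, r_outer = r_outer,
              lambda_t = lambda_t, lambda_r = lambda_r, lambda_l = lambda_l,
              d_lumen = d_lumen, d_background = d_background,
              S0_wall = S0_wall, S0_lumen = S0_lumen,
              S0_background = S0_background,
              bvals = bvals, scheme = scheme, snr = snr,
              seed = as.integer(seed))
  if (cfg$r_lumen <= 0 || cfg$r_outer <= cfg$r_lumen)
    stop("need outer radius > lumen radius > 0", call. = FALSE)
  half_fov <- cfg$n_pixels * cfg$spacing / 2
  if (cfg$r_outer >= half_fov)
    stop("vessel does not fit inside the image", call. = FALSE)
  if (cfg$lambda_t < cfg$lambda_r || cfg$lambda_r < 0)
    stop("need lambda_t >= lambda_r >= 0", call. = FALSE)
  if (!(cfg$snr > 0)) stop("SNR must be positive", call. = FALSE)
  if (!any(cfg$bvals == 0))
    stop("b-values must include 0 (the unweighted reference)", call. = FALSE)
  class(cfg) <- "phantom_config"
  cfg
}

# Geometry and ground-truth tensor field for a config. Tensors are
# stored as the 6 unique components of the 3x3 tensor; the in-plane
# wall tensor is lambda_t t t' + lambda_r r r' with t the unit tangent
# and r the unit radial direction at each voxel's polar angle.
phantom_truth <- function(cfg) {
  n <- cfg$n_pixels
  ix <- seq_len(n)
  px <- (matrix(ix, n, n) - cfg$center[1L]) * cfg$spacing
  py <- (matrix(ix, n, n, byrow = TRUE) - cfg$center[2L]) * cfg$spacing
  rad <- sqrt(px^2 + py^2)
  lumen <- rad < cfg$r_lumen
  wall <- rad >= cfg$r_lumen & rad <= cfg$r_outer
  phi <- atan2(py, px)
  cphi <- cos(phi); sphi <- sin(phi)
  tx <- -sphi; ty <- cphi                      # unit tangent
  Dxx <- matrix(cfg$d_background, n, n)
  Dyy <- matrix(cfg$d_background, n, n)
  Dzz <- matrix(cfg$d_background, n, n)
  Dxy <- matrix(0, n, n)
  Dxx[lumen] <- Dyy[lumen] <- Dzz[lumen] <- cfg$d_lumen
  Dxx[wall] <- (cfg$lambda_t * sphi^2 + cfg$lambda_r * cphi^2)[wall]
  Dyy[wall] <- (cfg$lambda_t * cphi^2 + cfg$lambda_r * sphi^2)[wall]
  Dxy[wall] <- ((cfg$lambda_r - cfg$lambda_t) * sphi * cphi)[wall]
  Dzz[wall] <- cfg$lambda_l
  S0 <- matrix(cfg$S0_background, n, n)
  S0[lumen] <- cfg$S0_lumen
  S0[wall] <- cfg$S0_wall
  structure(list(wall_mask = wall, lumen_mask = lumen,
                 Dxx = Dxx, Dyy = Dyy, Dzz = Dzz, Dxy = Dxy,
                 tangent_x = tx, tangent_y = ty, S0 = S0,
                 sigma = if (is.finite(cfg$snr)) cfg$S0_wall / cfg$snr else 0,
                 seed = cfg$seed, config = cfg),
            class = "phantom_truth")
}

#' Simulate the annular vessel-wall phantom
#'
#' Generates a single-slice diffusion-weighted stack from the analytic
#' tensor field of [phantom_config]: the signal for b-value `b` and unit
#' gradient `g` is `S0 exp(-b g' D g)`, with Rician noise
#' `sqrt((S + n1)^2 + n2^2)` (`n1, n2 ~ N(0, sigma^2)`,
#' `sigma = S0_wall / snr`) applied to the magnitude images.
#'
#' @param config A `phantom_config`.
#' @param directions_3d Optional n x 3 matrix of 3D unit directions. If
#'   supplied, the stack is simulated for these directions (using the
#'   full 3D tensor, including `lambda_l`) instead of the config's
#'   in-plane scheme.
#' @return A list with `stack` (a [dwi_stack]) and `truth`
#'   (a `phantom_truth`: masks, true tensor components, tangent field,
#'   noise sigma, seed).
#' @examples
#' ph <- make_phantom(phantom_config(n_pixels = 32L, snr = Inf))
#' sum(ph$truth$wall_mask)
#' @export
make_phantom <- function(config, directions_3d = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  truth <- phantom_truth(config)
  n <- config$n_pixels
  if (is.null(directions_3d)) {
    dirs <- cbind(config$scheme$in_plane_components, 0)
  } else {
    dirs <- matrix(directions_3d, ncol = 3L)
    nrm <- sqrt(rowSums(dirs^2))
    if (any(abs(nrm - 1) > 1e-8))
      stop("3D directions must be unit vectors", call. = FALSE)
  }
  bw <- config$bvals[config$bvals > 0]
  nb0 <- sum(config$bvals == 0)
  nmeas <- nb0 + length(bw) * nrow(dirs)
  data <- array(0, c(n, n, 1L, nmeas))
  bvals <- numeric(nmeas)
  bvecs <- matrix(0, 3L, nmeas)
  j <- 0L
  for (i0 in seq_len(nb0)) {
    j <- j + 1L
    data[, , 1L, j] <- truth$S0
  }
  for (k in seq_len(nrow(dirs))) {
    g <- dirs[k, ]
    # g' D g from the stored unique components
    adc <- g[1L]^2 * truth$Dxx + g[2L]^2 * truth$Dyy + g[3L]^2 * truth$Dzz +
      2 * g[1L] * g[2L] * truth$Dxy
    for (b in bw) {
      j <- j + 1L
      data[, , 1L, j] <- truth$S0 * exp(-b * adc)
      bvals[j] <- b
      bvecs[, j] <- g
    }
  }
  if (truth$sigma > 0) {
    set.seed(config$seed)
    n1 <- array(stats::rnorm(length(data), 0, truth$sigma), dim(data))
    n2 <- array(stats::rnorm(length(data), 0, truth$sigma), dim(data))
    data <- sqrt((data + n1)^2 + n2^2)
  }
  stack <- dwi_stack(data, bvals, bvecs, config$spacing,
                     meta = list(generator = "vwdti annular phantom",
                                 seed = config$seed, sigma = truth$sigma,
                                 snr = config$snr,
                                 lambda_t = config$lambda_t,
                                 lambda_r = config$lambda_r,
                                 r_lumen = config$r_lumen,
                                 r_outer = config$r_outer))
  list(stack = stack, truth = truth)
}

#' Simulate repeated acquisitions of the same phantom
#'
#' Produces `n_repeats` stacks sharing one ground truth but with
#' independent Rician noise realisations, emulating scan-rescan
#' repeatability experiments.
#'
#' @param config A `phantom_config`.
#' @param n_repeats Number of repeats (>= 2).
#' @param seeds Integer vector of distinct seeds, one per repeat
#'   (default `config$seed + 0:(n_repeats-1)`).
#' @return A list with `stacks` (list of [dwi_stack]) and the shared
#'   `truth`.
#' @export
make_repeatability_set <- function(config, n_repeats,
                                   seeds = config$seed + seq_len(n_repeats) - 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_repeats < 2L) stop("need at least 2 repeats", call. = FALSE)
  if (length(seeds) != n_repeats || anyDuplicated(seeds))
    stop("seeds must be distinct, one per repeat", call. = FALSE)
  out <- vector("list", n_repeats)
  truth <- NULL
  for (i in seq_len(n_repeats)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(seeds[i])
    ph <- make_phantom(cfg_i)
    out[[i]] <- ph$stack
    if (is.null(truth)) truth <- ph$truth
  }
  list(stacks = out, truth = truth)
}

#' Deterministic quasi-uniform hemisphere directions
#'
#' Fibonacci-lattice points on the upper unit hemisphere, a standard way
#' to obtain a well-conditioned multi-directional 3D diffusion-encoding
#' set (e.g. 30 directions) without optimisation.
#'
#' @param n Number of directions (>= 6 for 3D tensor estimation).
#' @return n x 3 matrix of unit vectors with nonnegative z.
#' @export
make_sphere_directions <- function(n) {
  stopifnot(n >= 6L)
  i <- seq_len(n) - 0.5
  z <- i / n                      # upper hemisphere only
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
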