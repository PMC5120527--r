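#' Design matrix for 2D tensor estimation
#'
#' For each in-plane unit direction `(gx, gy)` of a scheme the measured
#' ADC equals `gx^2 Dxx + gy^2 Dyy + 2 gx gy Dxy`, so the per-voxel ADC
#' vector `Y` relates to the tensor vector `d = [Dxx, Dyy, Dxy]` by
#' `Y = H d` with row i of `H` equal to `[gx_i^2, gy_i^2, 2 gx_i gy_i]`.
#'
#' @param scheme A `gradient_scheme`.
#' @return An n x 3 design matrix.
#' @export
build_design_matrix_2d <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  g <- scheme$in_plane_components
  H <- cbind(g[, 1L]^2, g[, 2L]^2, 2 * g[, 1L] * g[, 2L])
  colnames(H) <- c("xx", "yy", "xy")
  if (qr(H)$rank < 3L)
    stop("scheme has fewer than 3 distinct hemicycle angles: design matrix is rank deficient",
         call. = FALSE)
  H
}

#' Design matrix for 3D tensor estimation
#'
#' Row i is `[gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz]` for unit
#' direction i, mapping the 6-element tensor vector
#' `[Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]` to per-direction ADCs.
#'
#' @param directions n x 3 matrix of unit gradient directions.
#' @return An n x 6 design matrix.
#' @export
build_design_matrix_3d <- function(directions) {
  g <- matrix(directions, ncol = 3L)
  H <- cbind(g[, 1L]^2, g[, 2L]^2, g[, 3L]^2,
             2 * g[, 1L] * g[, 2L], 2 * g[, 1L] * g[, 3L],
             2 * g[, 2L] * g[, 3L])
  colnames(H) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  if (nrow(H) < 6L || qr(H)$rank < 6L)
    stop("directions are too few or too coplanar: 3D design matrix is rank deficient",
         call. = FALSE)
  H
}

#' Least-squares tensor solve
#'
#' Solves the overdetermined linear system `Y = H d` for the tensor
#' vector(s) `d` by rank-revealing QR least squares. `Y` may be a vector
#' (one voxel) or an n x nvox matrix (one column per voxel).
#'
#' @param Y Per-direction ADC vector, or matrix with one column per voxel.
#' @param H Design matrix from [build_design_matrix_2d] or
#'   [build_design_matrix_3d].
#' @return Tensor vector of length `ncol(H)`, or a `ncol(H)` x nvox matrix.
#' @export
solve_tensor <- function(Y, H) {
  p <- ncol(H)
  qrH <- qr(H)  # pivoted (rank-revealing) QR
  if (qrH$rank < p)
    stop("design matrix is rank deficient", call. = FALSE)
  ym <- if (is.matrix(Y)) Y else matrix(Y, ncol = 1L)
  if (nrow(ym) != nrow(H))
    stop("Y must have one ADC per design-matrix row", call. = FALSE)
  d <- qr.coef(qrH, ym)
  rownames(d) <- colnames(H)
  if (is.matrix(Y)) d else d[, 1L]
}

#' @rdname solve_tensor
#' @export
solve_tensor_2d <- function(Y, H) {
  stopifnot(ncol(H) == 3L)
  solve_tensor(Y, H)
}

#' @rdname solve_tensor
#' @export
solve_tensor_3d <- function(Y, H) {
  stopifnot(ncol(H) == 6L)
  solve_tensor(Y, H)
}

#' Closed-form eigendecomposition of symmetric 2x2 tensors
#'
#' For `d = [Dxx, Dyy, Dxy]` (one vector, or a 3 x nvox matrix) returns
#' sorted eigenvalues `l1 >= l2` and unit eigenvectors, using the closed
#' form for symmetric 2x2 matrices. Eigenvector signs are fixed so that
#' the first nonzero component is nonnegative; the degenerate isotropic
#' case returns `e1 = (1, 0)`.
#'
#' @param d Numeric length-3 vector or 3 x nvox matrix
#'   (rows Dxx, Dyy, Dxy).
#' @return A list with `l1`, `l2` (vectors) and `e1`, `e2`
#'   (2 x nvox matrices; plain length-2 vectors when `d` was a vector).
#' @export
eig2 <- function(d) {
  vec_in <- !is.matrix(d)
  dm <- if (vec_in) matrix(d, nrow = 3L) else d
  stopifnot(nrow(dm) == 3L)
  a <- dm[1L, ]; b <- dm[2L, ]; c <- dm[3L, ]
  tr <- a + b
  disc <- sqrt((a - b)^2 + 4 * c^2)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  # eigenvector of l1: pick the numerically larger of the two equivalent
  # forms (l1 - b, c) and (c, l1 - a)
  v1x <- l1 - b
  v1y <- c
  alt <- abs(c) > abs(v1x)
  v1x[alt] <- c[alt]
  v1y[alt] <- (l1 - a)[alt]
  iso <- disc <= .Machine$double.eps * pmax(abs(tr), 1e-300)
  v1x[iso] <- 1; v1y[iso] <- 0
  nrm <- sqrt(v1x^2 + v1y^2)
  zero <- nrm == 0
  v1x[zero] <- 1; v1y[zero] <- 0; nrm[zero] <- 1
  v1x <- v1x / nrm; v1y <- v1y / nrm
  # sign convention: first nonzero component nonnegative
  flip <- v1x < 0 | (v1x == 0 & v1y < 0)
  v1x[flip] <- -v1x[flip]; v1y[flip] <- -v1y[flip]
  # e2 orthogonal to e1, same convention
  v2x <- -v1y; v2y <- v1x
  flip2 <- v2x < 0 | (v2x == 0 & v2y < 0)
  v2x[flip2] <- -v2x[flip2]; v2y[flip2] <- -v2y[flip2]
  e1 <- rbind(v1x, v1y); e2 <- rbind(v2x, v2y)
  rownames(e1) <- rownames(e2) <- c("x", "y")
  if (vec_in)
    list(l1 = l1[[1L]], l2 = l2[[1L]], e1 = e1[, 1L], e2 = e2[, 1L])
  else
    list(l1 = l1, l2 = l2, e1 = e1, e2 = e2)
}

#' Two-dimensional fractional anisotropy
#'
#' `FA = (l1 - l2) / sqrt(l1^2 + l2^2)` for the 2D tensor: 0 for
#' isotropic in-plane diffusion, 1 when the minor eigenvalue vanishes.
#' Defined as 0 when both eigenvalues are zero.
#'
#' @param l1,l2 Eigenvalues with `l1 >= l2 >= 0` (vectors allowed).
#' @return FA value(s) in `[0, 1]`.
#' @examples
#' fa_2d(1.59e-3, 0.44e-3)  # 0.697
#' @export
fa_2d <- function(l1, l2) {
  if (any(l1 < l2)) stop("eigenvalues must satisfy l1 >= l2", call. = FALSE)
  den <- sqrt(l1^2 + l2^2)
  out <- ifelse(den == 0, 0, (l1 - l2) / den)
  out
}

#' Mean and radial diffusivity of the 2D tensor
#'
#' MD is the average of the two eigenvalues; RD is the minor (radially
#' oriented) eigenvalue `l2`.
#'
#' @inheritParams fa_2d
#' @return A list with `MD` and `RD` (mm^2/s).
#' @export
md_rd_2d <- function(l1, l2) {
  if (any(l1 < l2)) stop("eigenvalues must satisfy l1 >= l2", call. = FALSE)
  list(MD = (l1 + l2) / 2, RD = l2)
}

#' Three-dimensional fractional anisotropy
#'
#' Standard 3D FA,
#' `sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2) / sqrt(l1^2 + l2^2 + l3^2)`.
#'
#' @param l1,l2,l3 Sorted eigenvalues `l1 >= l2 >= l3 >= 0`, not all zero.
#' @return FA value(s) in `[0, 1]`.
#' @examples
#' fa_3d(1.07e-3, 0.64e-3, 0.62e-3)  # about 0.32
#' @export
fa_3d <- function(l1, l2, l3) {
  if (any(l1 < l2) || any(l2 < l3))
    stop("eigenvalues must satisfy l1 >= l2 >= l3", call. = FALSE)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  if (any(den == 0)) stop("eigenvalues must not all be zero", call. = FALSE)
  sqrt(0.5) * sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2) / den
}

#' Voxelwise 2D tensor pipeline
#'
#' Runs the full estimation chain on a diffusion-weighted stack: for each
#' masked voxel and each gradient direction, fit the mono-exponential
#' decay over the b-values of that direction (sharing the b = 0
#' measurements) to obtain the per-direction ADC vector `Y`; solve
#' `Y = H d` by least squares; eigendecompose; derive FA, MD, RD and the
#' principal-eigenvalue map. Voxels whose b = 0 signal falls below
#' `noise_floor`, and voxels with a negative minor eigenvalue (clamped to
#' zero for the scalar maps), are flagged.
#'
#' @param stack A `dwi_stack` (see [dwi_stack]).
#' @param scheme The `gradient_scheme` used for the acquisition.
#' @param mask Logical or 0/1 matrix of the in-plane image size; voxels
#'   outside are skipped. Default: all voxels.
#' @param noise_floor Minimum b = 0 signal for a voxel to be fitted
#'   (default 0: fit everything nonzero).
#' @param d_max Upper clamp for per-direction ADCs (see [fit_monoexp]).
#' @return A list of class `tensor_fit_2d` with elements `tensor`
#'   (`Dxx`, `Dyy`, `Dxy`, `l1`, `l2`, `e1x`, `e1y` matrices), `maps`
#'   (`FA`, `MD`, `RD`, `L1` matrices), `flags` (integer matrix: 0 ok,
#'   1 excluded/low signal, 2 negative eigenvalue clamped), `adc`
#'   (n_directions-deep array of per-direction ADC maps), and `scheme`.
#' @export
tensor_pipeline_2d <- function(stack, scheme, mask = NULL, noise_floor = 0,
                               d_max = 0.02) {
  stopifnot(inherits(stack, "dwi_stack"), inherits(scheme, "gradient_scheme"))
  dims <- dim(stack$data)
  nx <- dims[1L]; ny <- dims[2L]
  if (length(unique(stack$dir_index[stack$dir_index > 0])) != scheme$n_directions)
    stop("stack and scheme disagree on the number of diffusion directions",
         call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  mask <- matrix(as.logical(mask), nx, ny)
  if (!any(mask)) stop("mask selects no voxels", call. = FALSE)

  flat <- matrix(stack$data, nx * ny, dims[4L])  # voxels x measurements
  idx <- which(as.vector(mask))
  b0_cols <- which(stack$dir_index == 0L)
  if (length(b0_cols) == 0L)
    stop("stack contains no b = 0 reference measurement", call. = FALSE)
  s0 <- rowMeans(flat[, b0_cols, drop = FALSE])[idx]
  fit_ok <- s0 > noise_floor
  nv <- length(idx)

  H <- build_design_matrix_2d(scheme)
  Y <- matrix(NA_real_, scheme$n_directions, nv)
  clamped_any <- rep(FALSE, nv)
  for (k in seq_len(scheme$n_directions)) {
    cols <- which(stack$dir_index == k)
    if (length(cols) == 0L)
      stop(sprintf("no measurements for direction %d", k), call. = FALSE)
    bb <- c(rep(0, length(b0_cols)), stack$bvals[cols])
    S <- t(flat[idx, c(b0_cols, cols), drop = FALSE])
    f <- fit_monoexp_matrix(bb, S, d_max = d_max)
    Y[k, ] <- f$D
    clamped_any <- clamped_any | f$clamped
  }
  Y[, !fit_ok] <- NA_real_

  d <- matrix(NA_real_, 3L, nv)
  d[, fit_ok] <- solve_tensor_2d(Y[, fit_ok, drop = FALSE], H)
  eg <- eig2(d)
  neg <- !is.na(eg$l2) & eg$l2 < 0
  l1c <- pmax(eg$l1, 0); l2c <- pmax(eg$l2, 0)
  fa <- fa_2d(l1c, l2c)
  md <- (l1c + l2c) / 2

  blank <- matrix(NA_real_, nx, ny)
  put <- function(v) { m <- blank; m[idx] <- v; m }
  flags <- matrix(NA_integer_, nx, ny)
  flags[idx] <- ifelse(!fit_ok, 1L, ifelse(neg, 2L, 0L))
  adc <- array(NA_real_, c(nx, ny, scheme$n_directions))
  for (k in seq_len(scheme$n_directions)) {
    m <- blank; m[idx] <- Y[k, ]; adc[, , k] <- m
  }
  structure(list(
    tensor = list(Dxx = put(d[1L, ]), Dyy = put(d[2L, ]), Dxy = put(d[3L, ]),
                  l1 = put(eg$l1), l2 = put(eg$l2),
                  e1x = put(eg$e1[1L, ]), e1y = put(eg$e1[2L, ])),
    maps = list(FA = put(fa), MD = put(md), RD = put(l2c), L1 = put(l1c)),
    flags = flags,
    adc = adc,
    clamped_adc = put(as.numeric(clamped_any)),
    scheme = scheme), class = "tensor_fit_2d")
}

#' Voxelwise 3D tensor pipeline (reference)
#'
#' Same estimation chain as [tensor_pipeline_2d] but with a 3D direction
#' set and the 6-element tensor; used to validate the 2D reduction
#' against a conventional multi-directional acquisition. Eigenvalues are
#' reported sorted; each eigenvector's elevation angle relative to the
#' imaging plane is returned instead of an anatomical label, because
#' when two eigenvalues are close their anatomical assignment is
#' ambiguous.
#'
#' @param stack A `dwi_stack` whose `bvecs` hold 3D unit directions.
#' @param mask Optional logical matrix, as in [tensor_pipeline_2d].
#' @param noise_floor,d_max As in [tensor_pipeline_2d].
#' @return A list of class `tensor_fit_3d` with `l1`, `l2`, `l3` maps,
#'   `FA`, `MD` maps, per-eigenvector plane-elevation-angle maps
#'   `angle1`, `angle2`, `angle3` (degrees), and `flags`.
#' @export
tensor_pipeline_3d <- function(stack, mask = NULL, noise_floor = 0,
                               d_max = 0.02) {
  stopifnot(inherits(stack, "dwi_stack"))
  dims <- dim(stack$data)
  nx <- dims[1L]; ny <- dims[2L]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  mask <- matrix(as.logical(mask), nx, ny)
  flat <- matrix(stack$data, nx * ny, dims[4L])
  idx <- which(as.vector(mask))
  nv <- length(idx)
  b0_cols <- which(stack$dir_index == 0L)
  if (length(b0_cols) == 0L)
    stop("stack contains no b = 0 reference measurement", call. = FALSE)
  dirs_id <- sort(unique(stack$dir_index[stack$dir_index > 0L]))
  ndir <- length(dirs_id)
  dirs <- t(vapply(dirs_id, function(k)
    stack$bvecs[, which(stack$dir_index == k)[1L]], numeric(3L)))
  H <- build_design_matrix_3d(dirs)
  s0 <- rowMeans(flat[, b0_cols, drop = FALSE])[idx]
  fit_ok <- s0 > noise_floor
  Y <- matrix(NA_real_, ndir, nv)
  for (k in seq_len(ndir)) {
    cols <- which(stack$dir_index == dirs_id[k])
    bb <- c(rep(0, length(b0_cols)), stack$bvals[cols])
    S <- t(flat[idx, c(b0_cols, cols), drop = FALSE])
    Y[k, ] <- fit_monoexp_matrix(bb, S, d_max = d_max)$D
  }
  Y[, !fit_ok] <- NA_real_
  d <- matrix(NA_real_, 6L, nv)
  d[, fit_ok] <- solve_tensor_3d(Y[, fit_ok, drop = FALSE], H)
  lam <- matrix(NA_real_, 3L, nv)
  ang <- matrix(NA_real_, 3L, nv)
  for (j in seq_len(nv)) {
    if (!fit_ok[j]) next
    Dm <- matrix(c(d[1L, j], d[4L, j], d[5L, j],
                   d[4L, j], d[2L, j], d[6L, j],
                   d[5L, j], d[6L, j], d[3L, j]), 3L, 3L)
    e <- eigen(Dm, symmetric = TRUE)
    lam[, j] <- e$values
    ang[, j] <- angle_to_plane(t(e$vectors))
  }
  l1c <- pmax(lam[1L, ], 0); l2c <- pmax(lam[2L, ], 0); l3c <- pmax(lam[3L, ], 0)
  nz <- !is.na(l1c) & (l1c + l2c + l3c) > 0
  fa <- rep(NA_real_, nv)
  fa[nz] <- fa_3d(l1c[nz], l2c[nz], l3c[nz])
  blank <- matrix(NA_real_, nx, ny)
  put <- function(v) { m <- blank; m[idx] <- v; m }
  flags <- matrix(NA_integer_, nx, ny)
  flags[idx] <- ifelse(!fit_ok, 1L, ifelse(!is.na(lam[3L, ]) & lam[3L, ] < 0, 2L, 0L))
  structure(list(l1 = put(lam[1L, ]), l2 = put(lam[2L, ]), l3 = put(lam[3L, ]),
                 FA = put(fa), MD = put((l1c + l2c + l3c) / 3),
                 angle1 = put(ang[1L, ]), angle2 = put(ang[2L, ]),
                 angle3 = put(ang[3L, ]),
                 flags = flags), class = "tensor_fit_3d")
}

#' Red-green principal-direction image
#'
#' Encodes the principal eigenvector as colour (red = |x component|,
#' green = |y component|), scaled by FA — the 2D analogue of the familiar
#' RGB direction-encoded map. Background (flagged/unmasked) voxels are
#' black.
#'
#' @param fit A `tensor_fit_2d`.
#' @param path Output PNG file path.
#' @return The path, invisibly.
#' @export
write_rg_image <- function(fit, path) {
  stopifnot(inherits(fit, "tensor_fit_2d"))
  fa <- fit$maps$FA
  fa[is.na(fa)] <- 0
  r <- abs(fit$tensor$e1x) * fa
  g <- abs(fit$tensor$e1y) * fa
  r[is.na(r)] <- 0; g[is.na(g)] <- 0
  img <- array(0, c(nrow(fa), ncol(fa), 3L))
  img[, , 1L] <- pmin(r, 1); img[, , 2L] <- pmin(g, 1)
  png::writePNG(img, path)
  invisible(path)
}
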