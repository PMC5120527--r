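#' Construct a hemicycle diffusion gradient scheme
#'
#' Builds `n` unit diffusion-encoding directions evenly spaced on a
#' hemicycle (half circle) within the imaging plane, the sampling scheme
#' used for 2D tensor estimation in a plane perpendicular to the vessel's
#' longitudinal axis. Opposite directions are redundant for diffusion
#' weighting, so angles span `[0, pi)`.
#'
#' @param n Number of directions (>= 2; at least 3 are required for a
#'   full-rank 2D tensor design matrix). The in vivo protocol this package
#'   targets uses 18 directions, giving 10 degree spacing.
#' @param offset Angular offset in radians applied to every direction
#'   (default 0). Useful for rotational-invariance checks.
#' @param plane_normal Unit 3-vector giving the plane's normal in the
#'   scanner frame (the vessel's longitudinal axis). Default `c(0, 0, 1)`.
#' @param frame_label Text tag for the coordinate convention of the
#'   field of view (default `"prs"`).
#'
#' @return An object of class `gradient_scheme`: a list with
#'   `n_directions`, `angles` (radians), `in_plane_components` (n x 2
#'   matrix of unit `(gx, gy)` pairs), `plane_normal` and `frame_label`.
#' @examples
#' sch <- make_hemicycle_scheme(18)
#' diff(sch$angles)[1] * 180 / pi  # 10 degrees
#' @export
make_hemicycle_scheme <- function(n, offset = 0, plane_normal = c(0, 0, 1),
                                  frame_label = "prs") {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 2)
    stop("`n` must be an integer >= 2: fewer directions leave the 2D tensor unidentifiable",
         call. = FALSE)
  n <- as.integer(n)
  plane_normal <- .unit3(plane_normal)
  theta <- offset + seq(0L, n - 1L) * pi / n
  gxy <- cbind(gx = cos(theta), gy = sin(theta))
  structure(
    list(n_directions = n,
         angles = theta,
         in_plane_components = gxy,
         plane_normal = plane_normal,
         frame_label = frame_label),
    class = "gradient_scheme")
}

#' Rotate a gradient scheme in-plane
#'
#' @param scheme A `gradient_scheme`.
#' @param angle Rotation angle in radians (counter-clockwise).
#' @return A rotated `gradient_scheme`.
#' @export
rotate_scheme <- function(scheme, angle) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  out <- scheme
  out$angles <- scheme$angles + angle
  out$in_plane_components <- scheme$in_plane_components %*% t(R)
  colnames(out$in_plane_components) <- c("gx", "gy")
  out
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("Hemicycle gradient scheme: %d in-plane directions (%s frame)\n",
              x$n_directions, x$frame_label))
  cat(sprintf("  angular spacing %.3f deg, plane normal [%.3f %.3f %.3f]\n",
              180 / x$n_directions, x$plane_normal[1], x$plane_normal[2],
              x$plane_normal[3]))
  invisible(x)
}

# Deterministic orthonormal in-plane basis (u, v) for the plane with the
# given normal: Gram-Schmidt of the x-axis against the normal, with the
# y-axis as fallback when the normal is (anti)parallel to x.
plane_basis <- function(normal) {
  normal <- .unit3(normal)
  ref <- c(1, 0, 0)
  if (abs(sum(ref * normal)) > 1 - 1e-8) ref <- c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  list(u = u, v = v, normal = normal)
}

#' Lift in-plane directions to scanner-frame 3D vectors
#'
#' Embeds each `(gx, gy)` pair of a scheme into 3D scanner coordinates so
#' that all directions lie in the plane perpendicular to `plane_normal`.
#' The in-plane basis is a deterministic Gram-Schmidt construction (see
#' [plane_basis]), so direction files are reproducible.
#'
#' @param scheme A `gradient_scheme`.
#' @param plane_normal Unit 3-vector normal of the target plane; defaults
#'   to the scheme's own `plane_normal`.
#' @return An n x 3 matrix of unit vectors, each orthogonal to
#'   `plane_normal`.
#' @export
lift_to_scanner_frame <- function(scheme, plane_normal = scheme$plane_normal) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  basis <- plane_basis(plane_normal)
  g <- scheme$in_plane_components
  out <- g[, 1L] %o% basis$u + g[, 2L] %o% basis$v
  colnames(out) <- c("x", "y", "z")
  out
}

#' Project scanner-frame vectors back into the plane
#'
#' Inverse of [lift_to_scanner_frame] for vectors lying in the plane:
#' returns the `(gx, gy)` coordinates in the plane's deterministic basis.
#'
#' @param vectors n x 3 matrix of scanner-frame vectors.
#' @param plane_normal Unit 3-vector plane normal.
#' @return n x 2 matrix of in-plane coordinates.
#' @export
project_to_plane <- function(vectors, plane_normal) {
  basis <- plane_basis(plane_normal)
  vectors <- matrix(vectors, ncol = 3L)
  cbind(gx = as.vector(vectors %*% basis$u),
        gy = as.vector(vectors %*% basis$v))
}

#' Signed elevation angle of a vector relative to the xy-plane
#'
#' Computes `pi/2 - arccos(z / |v|)` in degrees: 0 for in-plane vectors,
#' +90 for the +z axis, negative below the plane. Used to summarise how
#' far a principal diffusion direction tilts out of the imaging plane.
#'
#' @param v A 3-vector, or an n x 3 matrix of vectors (rows).
#' @return Signed angle(s) in degrees, in `[-90, 90]`.
#' @examples
#' angle_to_plane(c(0, 0, 2))   # 90
#' angle_to_plane(c(1, 1, sqrt(2)))  # 45
#' @export
angle_to_plane <- function(v) {
  v <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  stopifnot(ncol(v) == 3L)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0))
    stop("zero vector has no elevation angle", call. = FALSE)
  ang <- (pi / 2 - acos(pmin(1, pmax(-1, v[, 3L] / nrm)))) * 180 / pi
  if (nrow(v) == 1L) ang[[1L]] else ang
}

.unit3 <- function(v) {
  if (length(v) != 3L || !all(is.finite(v)))
    stop("plane normal must be a finite 3-vector", call. = FALSE)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12)
    stop("plane normal must have nonzero norm", call. = FALSE)
  v / nrm
}
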