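#' Diffusion-weighted image stack
#'
#' Container for a single-slice diffusion-weighted series: a 4D array
#' (rows x cols x 1 x n_measurements) with per-measurement b-values and
#' gradient directions. Measurements with b = 0 (or a zero gradient
#' column) form the unweighted reference; the remaining measurements are
#' grouped into directions by their gradient vector.
#'
#' @param data 4D numeric array, nonnegative intensities.
#' @param bvals Numeric vector of b-values (s/mm^2), one per measurement.
#' @param bvecs 3 x n_measurements matrix of gradient directions
#'   (FSL-style; zero columns for b = 0).
#' @param spacing In-plane pixel spacing in mm (length 1 or 2).
#' @param meta Optional named list of provenance metadata (seed, config
#'   hash, ...).
#' @return An object of class `dwi_stack` with an additional `dir_index`
#'   element: integer per measurement, 0 for b = 0 and 1..n_directions
#'   for each distinct gradient direction.
#' @export
dwi_stack <- function(data, bvals, bvecs, spacing, meta = list()) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3L])
  stopifnot(length(dim(data)) == 4L)
  nm <- dim(data)[4L]
  if (length(bvals) != nm || ncol(bvecs) != nm)
    stop("b-value/b-vector count does not match the number of measurements",
         call. = FALSE)
  if (any(data < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (any(spacing <= 0)) stop("pixel spacing must be positive", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  nrm <- sqrt(colSums(bvecs^2))
  is_b0 <- bvals == 0 | nrm < 1e-6
  bad <- !is_b0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop(sprintf("gradient column(s) %s are not unit norm",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  dir_index <- integer(nm)
  seen <- NULL
  for (i in which(!is_b0)) {
    v <- bvecs[, i]
    hit <- 0L
    if (!is.null(seen)) {
      dd <- colSums((seen - v)^2)
      if (min(dd) < 1e-10) hit <- which.min(dd)
    }
    if (hit == 0L) {
      seen <- cbind(seen, v)
      hit <- ncol(seen)
    }
    dir_index[i] <- hit
  }
  structure(list(data = data, bvals = as.numeric(bvals), bvecs = bvecs,
                 dir_index = dir_index, spacing = spacing, meta = meta),
            class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI stack: %d x %d x %d, %d measurements (%d b0, %d directions)\n",
              d[1L], d[2L], d[3L], d[4L], sum(x$dir_index == 0L),
              length(unique(x$dir_index[x$dir_index > 0L]))))
  cat(sprintf("  b-values: %s s/mm^2; spacing %.3g x %.3g mm\n",
              paste(sort(unique(x$bvals)), collapse = ", "),
              x$spacing[1L], x$spacing[2L]))
  invisible(x)
}

#' Read and write FSL-style b-value / b-vector tables
#'
#' `bval` files hold one whitespace-separated row of b-values; `bvec`
#' files hold three rows (x, y, z components), one column per
#' measurement. Unit norm is enforced on write and validated within
#' 1e-6 on read for weighted columns.
#'
#' @param path File path.
#' @param bvals Numeric vector of b-values.
#' @param bvecs 3 x n matrix of directions.
#' @return `read_bval`: numeric vector. `read_bvec`: 3 x n matrix.
#' @name bval_bvec
NULL

#' @rdname bval_bvec
#' @export
write_bval <- function(bvals, path) {
  writeLines(paste(format(bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname bval_bvec
#' @export
read_bval <- function(path) {
  if (!file.exists(path)) stop("bval file not found: ", path, call. = FALSE)
  scan(path, quiet = TRUE)
}

#' @rdname bval_bvec
#' @export
write_bvec <- function(bvecs, path) {
  stopifnot(nrow(bvecs) == 3L)
  nrm <- sqrt(colSums(bvecs^2))
  live <- nrm > 1e-12
  bvecs[, live] <- sweep(bvecs[, live, drop = FALSE], 2L, nrm[live], "/")
  con <- file(path, "w")
  on.exit(close(con))
  for (r in 1:3)
    writeLines(paste(format(bvecs[r, ], trim = TRUE, digits = 15),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname bval_bvec
#' @export
read_bvec <- function(path) {
  if (!file.exists(path)) stop("bvec file not found: ", path, call. = FALSE)
  rows <- lapply(readLines(path), function(l) scan(text = l, quiet = TRUE))
  rows <- rows[lengths(rows) > 0L]
  if (length(rows) != 3L)
    stop("bvec file must have exactly 3 rows: ", path, call. = FALSE)
  if (length(unique(lengths(rows))) != 1L)
    stop("bvec rows have unequal lengths: ", path, call. = FALSE)
  m <- do.call(rbind, rows)
  nrm <- sqrt(colSums(m^2))
  bad <- nrm > 1e-6 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop(sprintf("bvec file %s: column(s) %s are not unit norm", path,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  m
}

#' Read a diffusion-weighted series from NIfTI + bval/bvec
#'
#' @param nifti_path Path to a 4D NIfTI image.
#' @param bval_path,bvec_path Companion FSL-style tables.
#' @return A list with `stack` (a [dwi_stack]) and, when the directions
#'   are in-plane, `scheme` (a `gradient_scheme` reconstructed from the
#'   weighted directions; `NULL` otherwise).
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(nifti_path)
  bvals <- read_bval(bval_path)
  bvecs <- read_bvec(bvec_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) {
    dim(arr) <- c(dim(arr), 1L, 1L)
  } else if (length(dim(arr)) == 3L) {
    dim(arr) <- c(dim(arr)[1:2], 1L, dim(arr)[3L])
  }
  if (dim(arr)[4L] != length(bvals))
    stop(sprintf("measurement count mismatch: image has %d volumes but %s lists %d b-values",
                 dim(arr)[4L], bval_path, length(bvals)), call. = FALSE)
  if (ncol(bvecs) != length(bvals))
    stop(sprintf("measurement count mismatch: %s has %d columns but %s lists %d b-values",
                 bvec_path, ncol(bvecs), bval_path, length(bvals)),
         call. = FALSE)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  spacing <- pd[1:2]
  stack <- dwi_stack(arr, bvals, bvecs, spacing,
                     meta = list(source = nifti_path))
  scheme <- NULL
  wt <- stack$dir_index > 0L
  if (any(wt) && all(abs(bvecs[3L, wt]) < 1e-9)) {
    firsts <- vapply(sort(unique(stack$dir_index[wt])),
                     function(k) which(stack$dir_index == k)[1L], integer(1L))
    g <- t(bvecs[1:2, firsts, drop = FALSE])
    scheme <- make_hemicycle_scheme(max(2L, nrow(g)))
    scheme$n_directions <- nrow(g)
    scheme$in_plane_components <- g
    colnames(scheme$in_plane_components) <- c("gx", "gy")
    scheme$angles <- atan2(g[, 2L], g[, 1L]) %% pi
  }
  list(stack = stack, scheme = scheme)
}

#' Write a diffusion-weighted series as NIfTI + bval/bvec
#'
#' @param stack A [dwi_stack].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec` and, if the stack carries
#'   provenance metadata, `<prefix>_provenance.json`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dwi <- function(stack, prefix) {
  stopifnot(inherits(stack, "dwi_stack"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(stack$data)
  RNifti::pixdim(img) <- c(stack$spacing, 1, 1)
  RNifti::writeNifti(img, nii, datatype = "double")
  write_bval(stack$bvals, paste0(prefix, ".bval"))
  write_bvec(stack$bvecs, paste0(prefix, ".bvec"))
  paths <- c(nifti = nii, bval = paste0(prefix, ".bval"),
             bvec = paste0(prefix, ".bvec"))
  if (length(stack$meta)) {
    pj <- paste0(prefix, "_provenance.json")
    jsonlite::write_json(stack$meta, pj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, provenance = pj)
  }
  invisible(paths)
}

#' Write scalar maps as NIfTI volumes
#'
#' @param maps Named list of 2D matrices (e.g. the `maps` element of a
#'   `tensor_fit_2d`).
#' @param prefix Output path prefix; each map goes to
#'   `<prefix>_<name>.nii.gz`.
#' @param spacing In-plane pixel spacing in mm.
#' @return Named character vector of paths, invisibly.
#' @export
write_maps <- function(maps, prefix, spacing = c(1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  paths <- character(0)
  for (nm in names(maps)) {
    p <- sprintf("%s_%s.nii.gz", prefix, nm)
    img <- RNifti::asNifti(maps[[nm]])
    RNifti::pixdim(img) <- c(spacing, 1)
    RNifti::writeNifti(img, p, datatype = "double")
    paths[nm] <- p
  }
  invisible(paths)
}

# Pad (or keep) one axis of a centred-DC spectrum. X is the full FFT of
# the source (R convention, DC at index 1); returns the spectrum with
# `axis` grown to M rows, splitting the Nyquist bin of an even-sized
# source half-and-half between +/- Nyquist so the padded spectrum stays
# Hermitian and the inverse transform real.
.pad_spectrum_axis <- function(X, M, axis) {
  m <- dim(X)[axis]
  if (M == m) return(X)
  dims <- dim(X)
  out_dims <- dims
  out_dims[axis] <- M
  out <- array(0 + 0i, out_dims)
  k <- 0:(m - 1)
  f <- ifelse(k <= (m - 1) %/% 2, k, k - m)     # signed frequency per bin
  tgt <- ifelse(f >= 0, f + 1L, M + f + 1L)      # 1-based target index
  wt <- rep(1, m)
  if (m %% 2L == 0L) {
    nyq <- which(f == -m %/% 2L)
    wt[nyq] <- 0.5
  }
  ix_src <- ix_tgt <- list(seq_len(dims[1L]), seq_len(dims[2L]))
  for (j in seq_along(k)) {
    ix_src[[axis]] <- j
    ix_tgt[[axis]] <- tgt[j]
    out[ix_tgt[[1L]], ix_tgt[[2L]]] <-
      out[ix_tgt[[1L]], ix_tgt[[2L]]] + wt[j] * X[ix_src[[1L]], ix_src[[2L]]]
    if (wt[j] != 1) {  # mirror half of the Nyquist bin to +Nyquist
      ix_tgt[[axis]] <- m %/% 2L + 1L
      out[ix_tgt[[1L]], ix_tgt[[2L]]] <-
        out[ix_tgt[[1L]], ix_tgt[[2L]]] +
        wt[j] * X[ix_src[[1L]], ix_src[[2L]]]
    }
  }
  out
}

#' Zero-filling (Fourier) interpolation of a 2D image
#'
#' Upsamples an image by symmetric zero-padding of its Fourier spectrum:
#' forward FFT, embed the spectrum centred at DC into the larger target
#' grid (splitting the Nyquist row/column of even-sized sources to keep
#' the spectrum Hermitian), inverse FFT, magnitude. Intensities are
#' scaled so the image mean is preserved. This is the interpolation
#' conventionally applied to magnitude DWI data before fitting; note it
#' correlates noise between neighbouring pixels.
#'
#' @param image 2D numeric matrix.
#' @param target_shape Integer vector `c(rows, cols)`, each at least the
#'   source size.
#' @return Interpolated matrix of size `target_shape`.
#' @export
zero_fill_interpolate <- function(image, target_shape) {
  stopifnot(is.matrix(image), length(target_shape) == 2L)
  m <- nrow(image); n <- ncol(image)
  M <- as.integer(target_shape[1L]); N <- as.integer(target_shape[2L])
  if (M < m || N < n)
    stop("target shape must be at least the source shape in every axis",
         call. = FALSE)
  X <- stats::fft(image)
  Xp <- .pad_spectrum_axis(X, M, 1L)
  Xp <- .pad_spectrum_axis(Xp, N, 2L)
  y <- stats::fft(Xp, inverse = TRUE) / (m * n)
  Mod(matrix(y, M, N))
}
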