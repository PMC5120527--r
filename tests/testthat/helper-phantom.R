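# Small phantom configurations used across tests. The default-geometry
# phantom (carotid-like) is small; validation tests that need many wall
# voxels use a larger, aorta-like ring.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_pixels = 48L, snr = Inf), list(...))
  do.call(phantom_config, args)
}

ring_config <- function(...) {
  # aorta-like ring: ~400 wall voxels at 0.55 mm spacing
  args <- utils::modifyList(list(n_pixels = 48L, r_lumen = 5, r_outer = 8),
                            list(...))
  do.call(phantom_config, args)
}

# mean FA over cleanly fitted wall voxels of one stack
wall_mean_fa <- function(stack, scheme, truth) {
  fit <- tensor_pipeline_2d(stack, scheme, mask = truth$wall_mask)
  mean(fit$maps$FA[fit$flags == 0L], na.rm = TRUE)
}

# mean absolute angle (degrees) between estimated principal eigenvector
# and the true wall tangent
wall_angle_error <- function(fit, truth) {
  w <- truth$wall_mask & fit$flags == 0L
  dots <- abs(fit$tensor$e1x[w] * truth$tangent_x[w] +
                fit$tensor$e1y[w] * truth$tangent_y[w])
  mean(acos(pmin(1, dots)) * 180 / pi)
}

# 90-degree rotation about the DFT grid origin (the rotation that the
# periodic Fourier representation of an image actually supports)
rot90_periodic <- function(a) {
  m <- nrow(a); n <- ncol(a)
  out <- matrix(0, n, m)
  for (u in 0:(n - 1))
    for (v in 0:(m - 1))
      out[u + 1, v + 1] <- a[v + 1, ((-u) %% n) + 1]
  out
}
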