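test_that("2D design matrix rows are the squared gradient components", {
  sch <- make_hemicycle_scheme(4)  # 0, 45, 90, 135 degrees
  H <- build_design_matrix_2d(sch)
  expect_equal(unname(H[1, ]), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(unname(H[3, ]), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(unname(H[2, ]), c(0.5, 0.5, 1.0), tolerance = 1e-12)

  degen <- make_hemicycle_scheme(4)
  degen$in_plane_components <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0), 4, 2,
                                      byrow = TRUE)
  expect_error(build_design_matrix_2d(degen), "rank deficient")
})

test_that("3D design matrix rows follow the 6-component convention", {
  expect_error(build_design_matrix_3d(diag(3)), "rank deficient")
  dirs <- make_sphere_directions(30)
  H <- build_design_matrix_3d(dirs)
  expect_equal(unname(H[, 1] + H[, 2] + H[, 3]), rep(1, 30), tolerance = 1e-12)
  expect_true(is.finite(kappa(H, exact = TRUE)))
  # round-trips a known symmetric tensor through the ADC projection
  D <- matrix(c(1.1, 0.2, 0.1, 0.2, 0.8, -0.1, 0.1, -0.1, 0.6), 3, 3) * 1e-3
  Y <- vapply(seq_len(30), function(i) dirs[i, ] %*% D %*% dirs[i, ],
              numeric(1))
  d <- solve_tensor_3d(Y, H)
  expect_equal(unname(d), c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3],
                            D[2, 3]), tolerance = 1e-12)
  g <- matrix(c(1, 0, 0, 0, 0, 1), 2, 3, byrow = TRUE)
  Hg <- build_design_matrix_3d(rbind(g, make_sphere_directions(8)))
  expect_equal(unname(Hg[1, ]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(Hg[2, ]), c(0, 0, 1, 0, 0, 0))
})

test_that("least-squares tensor solve matches the normal-equations oracle", {
  sch <- make_hemicycle_scheme(18)
  H <- build_design_matrix_2d(sch)
  d_true <- c(1.5e-3, 0.5e-3, 0.3e-3)
  expect_equal(unname(solve_tensor_2d(as.vector(H %*% d_true), H)), d_true,
               tolerance = 1e-12)
  # isotropic ADC profile gives a diagonal isotropic tensor
  expect_equal(unname(solve_tensor_2d(rep(1.1e-3, 18), H)),
               c(1.1e-3, 1.1e-3, 0), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:20) {
    Y <- as.vector(H %*% d_true) + rnorm(18, 0, 1e-4)
    d <- solve_tensor_2d(Y, H)
    d_ne <- solve(crossprod(H), crossprod(H, Y))  # normal equations oracle
    expect_equal(unname(d), as.vector(d_ne), tolerance = 1e-10)
  }
  expect_error(solve_tensor_2d(rep(1, 3), matrix(c(1, 1, 1, 0, 0, 0,
                                                   0, 0, 0), 3, 3)),
               "rank deficient")
})

test_that("closed-form 2x2 eigendecomposition matches a generic solver", {
  e <- eig2(c(2e-3, 1e-3, 0))
  expect_equal(c(e$l1, e$l2), c(2e-3, 1e-3))
  expect_equal(unname(e$e1), c(1, 0))

  e <- eig2(c(1e-3, 1e-3, 0.5e-3))
  expect_equal(c(e$l1, e$l2), c(1.5e-3, 0.5e-3), tolerance = 1e-12)
  expect_equal(unname(e$e1), c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)

  # degenerate isotropic tensor: conventional eigenvector
  e <- eig2(c(1e-3, 1e-3, 0))
  expect_equal(unname(e$e1), c(1, 0))

  set.seed(2)
  d <- rbind(rnorm(1000), rnorm(1000), rnorm(1000))
  eg <- eig2(d)
  for (j in 1:1000) {
    A <- matrix(c(d[1, j], d[3, j], d[3, j], d[2, j]), 2, 2)
    ref <- eigen(A, symmetric = TRUE)
    expect_equal(c(eg$l1[j], eg$l2[j]), ref$values, tolerance = 1e-10)
    # vectors agree up to sign
    expect_equal(abs(sum(eg$e1[, j] * ref$vectors[, 1])), 1, tolerance = 1e-10)
    # orthogonality, unit norm, trace identity, sign convention
    expect_lt(abs(sum(eg$e1[, j] * eg$e2[, j])), 1e-10)
    expect_equal(eg$l1[j] + eg$l2[j], d[1, j] + d[2, j], tolerance = 1e-10)
    expect_gte(eg$e1[1, j], 0)
  }
})

test_that("2D FA follows its closed form with sane conventions", {
  expect_equal(round(fa_2d(1.59e-3, 0.44e-3), 3), 0.697)
  expect_equal(fa_2d(1e-3, 1e-3), 0)
  expect_equal(fa_2d(1e-3, 0), 1)
  expect_equal(fa_2d(0, 0), 0)
  expect_error(fa_2d(1e-3, 2e-3), "l1 >= l2")
  set.seed(8)
  l1 <- abs(rnorm(100)); l2 <- runif(100) * l1
  fa <- fa_2d(l1, l2)
  expect_true(all(fa >= 0 & fa <= 1))
})

test_that("MD and RD derive from the eigenvalues", {
  m <- md_rd_2d(2.29e-3, 0.71e-3)
  expect_equal(m$MD, 1.50e-3)
  expect_equal(m$RD, 0.71e-3)
  m <- md_rd_2d(1.10e-3, 0.65e-3)
  expect_equal(m$MD, 0.875e-3)
  m <- md_rd_2d(1.3e-3, 1.3e-3)
  expect_equal(m$MD, 1.3e-3)
  expect_equal(m$RD, 1.3e-3)
})

test_that("3D FA follows the standard formula", {
  expect_equal(fa_3d(1e-3, 1e-3, 1e-3), 0)
  expect_equal(fa_3d(1e-3, 0, 0), 1)
  expect_equal(round(fa_3d(1.07e-3, 0.64e-3, 0.62e-3), 2), 0.32)
  expect_error(fa_3d(1e-3, 2e-3, 0.5e-3), "l1 >= l2")
})

test_that("pipeline recovers the phantom tensor field exactly without noise", {
  cfg <- tiny_config()
  ph <- make_phantom(cfg)
  fit <- tensor_pipeline_2d(ph$stack, cfg$scheme, mask = ph$truth$wall_mask)
  w <- ph$truth$wall_mask
  expect_lt(max(abs(fit$tensor$Dxx[w] - ph$truth$Dxx[w])), 1e-15)
  expect_lt(max(abs(fit$tensor$Dyy[w] - ph$truth$Dyy[w])), 1e-15)
  expect_lt(max(abs(fit$tensor$Dxy[w] - ph$truth$Dxy[w])), 1e-15)
  expect_equal(unique(round(fit$maps$FA[w], 9)),
               round(fa_2d(cfg$lambda_t, cfg$lambda_r), 9))
  # MD equals trace/2 computed directly from the tensor components
  expect_lt(max(abs(fit$maps$MD[w] -
                      (fit$tensor$Dxx[w] + fit$tensor$Dyy[w]) / 2)), 1e-12)
})

test_that("two-stage estimate equals a one-stage log-linear fit without noise", {
  cfg <- tiny_config()
  ph <- make_phantom(cfg)
  w <- which(ph$truth$wall_mask)
  fit <- tensor_pipeline_2d(ph$stack, cfg$scheme, mask = ph$truth$wall_mask)
  H <- build_design_matrix_2d(cfg$scheme)
  # one-stage oracle: ADC from the log-ratio at a single b, then solve
  flat <- matrix(ph$stack$data, prod(dim(ph$stack$data)[1:2]),
                 dim(ph$stack$data)[4])
  s0 <- flat[w, ph$stack$dir_index == 0L]
  for (j in seq_len(min(length(w), 25))) {
    Y <- vapply(1:cfg$scheme$n_directions, function(k) {
      col <- which(ph$stack$dir_index == k & ph$stack$bvals == 600)
      -log(flat[w[j], col] / s0[j]) / 600
    }, numeric(1))
    d_oracle <- solve_tensor_2d(Y, H)
    d_fit <- c(fit$tensor$Dxx[w[j]], fit$tensor$Dyy[w[j]],
               fit$tensor$Dxy[w[j]])
    expect_equal(d_fit, unname(d_oracle), tolerance = 1e-10)
  }
})

test_that("scalar maps are invariant to an in-plane rotation of the scheme", {
  cfg <- tiny_config()
  ph <- make_phantom(cfg)
  fit <- tensor_pipeline_2d(ph$stack, cfg$scheme, mask = ph$truth$wall_mask)
  cfg_rot <- tiny_config(scheme = rotate_scheme(cfg$scheme, pi / 6))
  ph_rot <- make_phantom(cfg_rot)
  fit_rot <- tensor_pipeline_2d(ph_rot$stack, cfg_rot$scheme,
                                mask = ph_rot$truth$wall_mask)
  w <- ph$truth$wall_mask
  expect_lt(max(abs(fit$maps$FA[w] - fit_rot$maps$FA[w])), 1e-9)
  expect_lt(max(abs(fit$maps$MD[w] - fit_rot$maps$MD[w])), 1e-9)
  expect_lt(max(abs(fit$maps$RD[w] - fit_rot$maps$RD[w])), 1e-9)
  # same tensor field, so the principal directions agree too
  dots <- abs(fit$tensor$e1x[w] * fit_rot$tensor$e1x[w] +
                fit$tensor$e1y[w] * fit_rot$tensor$e1y[w])
  expect_lt(max(abs(dots - 1)), 1e-9)
})

test_that("pipeline rejects inconsistent inputs with clear messages", {
  cfg <- tiny_config()
  ph <- make_phantom(cfg)
  expect_error(tensor_pipeline_2d(ph$stack, make_hemicycle_scheme(6)),
               "disagree")
  expect_error(tensor_pipeline_2d(ph$stack, cfg$scheme,
                                  mask = matrix(FALSE, 48, 48)),
               "no voxels")
})
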