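#' Mono-exponential diffusion signal
#'
#' Evaluates `S(b) = S0 * exp(-b * D)`, the mono-exponential decay of the
#' diffusion-weighted MR signal with b-value `b` (s/mm^2) and apparent
#' diffusion coefficient `D` (mm^2/s).
#'
#' @param S0 Reference signal at b = 0 (arbitrary units, >= 0).
#' @param D Apparent diffusion coefficient (mm^2/s, >= 0).
#' @param b b-value(s) (s/mm^2, >= 0).
#' @return Signal intensity, recycled over `b`.
#' @examples
#' predict_signal(100, 2.11e-3, 605)  # about 27.9
#' @export
predict_signal <- function(S0, D, b) {
  if (any(b < 0)) stop("b-values must be nonnegative", call. = FALSE)
  if (any(D < 0) || any(S0 < 0))
    stop("S0 and D must be nonnegative", call. = FALSE)
  S0 * exp(-b * D)
}

# Vectorised damped (Levenberg-Marquardt) least squares for the
# two-parameter model S = S0 exp(-b D), solved simultaneously for many
# voxels. `signals` is an nb x nvox matrix. The 2x2 normal equations are
# solved in closed form per voxel, so the cost is a handful of
# elementwise matrix operations per iteration.
fit_monoexp_matrix <- function(b_values, signals,
                               d_max = 0.02, max_iter = 200L, tol = 1e-10) {
  b <- as.numeric(b_values)
  S <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1L)
  nb <- length(b)
  if (nrow(S) != nb)
    stop("signals must have one row per b-value", call. = FALSE)
  if (length(unique(b)) < 2L)
    stop("at least 2 distinct b-values are required", call. = FALSE)
  if (any(S < 0)) stop("signals must be nonnegative", call. = FALSE)
  dead <- colSums(S) == 0
  if (!is.matrix(signals) && dead[1L])
    stop("all-zero signal: nothing to fit", call. = FALSE)
  nv <- ncol(S)

  # log-linear WLS initialisation: minimise sum w (ln S - (ln S0 - b D))^2
  # with w = S^2 (first-order noise propagation of the log transform)
  logS <- log(pmax(S, 1e-12))
  w <- S^2
  sw <- colSums(w)
  swb <- colSums(w * b)
  swb2 <- colSums(w * b^2)
  swy <- colSums(w * logS)
  swby <- colSums(w * b * logS)
  det0 <- sw * swb2 - swb^2
  det0[det0 <= 0 | dead] <- NA
  D <- (swb * swy - sw * swby) / det0
  a <- (swb2 * swy - swb * swby) / det0
  D[!is.finite(D)] <- 0
  a[!is.finite(a)] <- 0
  D <- pmin(pmax(D, 0), d_max)
  S0 <- exp(a)
  S0[dead] <- 0

  cost_of <- function(S0, D) {
    m <- S0 * exp(outer(-b, D))
    colSums((S - m)^2)
  }
  cost <- cost_of(S0, D)
  lambda <- rep(1e-3, nv)
  converged <- dead  # nothing to do for dead voxels
  for (it in seq_len(max_iter)) {
    active <- !converged
    if (!any(active)) break
    E <- exp(outer(-b, D))                 # nb x nv
    M <- sweep(E, 2L, S0, "*")
    r <- S - M
    # J1 = dM/dS0 = E ; J2 = dM/dD = -b * M
    J2 <- -b * M
    a11 <- colSums(E * E)
    a12 <- colSums(E * J2)
    a22 <- colSums(J2 * J2)
    g1 <- colSums(E * r)
    g2 <- colSums(J2 * r)
    A11 <- a11 * (1 + lambda)
    A22 <- a22 * (1 + lambda)
    det <- A11 * A22 - a12^2
    ok <- det > 0 & active
    d1 <- d2 <- numeric(nv)
    d1[ok] <- (A22[ok] * g1[ok] - a12[ok] * g2[ok]) / det[ok]
    d2[ok] <- (A11[ok] * g2[ok] - a12[ok] * g1[ok]) / det[ok]
    S0_new <- pmax(S0 + d1, 0)
    D_new <- pmin(pmax(D + d2, 0), d_max)
    cost_new <- cost_of(S0_new, D_new)
    better <- ok & (cost_new <= cost)
    rel <- abs(cost - cost_new) / pmax(cost, .Machine$double.xmin)
    newly <- better & (rel < tol | cost_new < 1e-28)
    S0[better] <- S0_new[better]
    D[better] <- D_new[better]
    cost[better] <- cost_new[better]
    lambda[better] <- pmax(lambda[better] / 3, 1e-12)
    worse <- active & !better
    lambda[worse] <- pmin(lambda[worse] * 4, 1e10)
    converged <- converged | newly | (active & !ok)
  }
  clamped <- (D >= d_max - 1e-15) | (D <= 0 & !dead &
                                       cost > 1e-20 * pmax(colSums(S^2), 1))
  list(S0 = S0, D = D,
       residual_norm = sqrt(pmax(cost, 0)),
       converged = converged | cost < 1e-24,
       clamped = clamped,
       dead = dead)
}

#' Fit the mono-exponential diffusion model to one signal series
#'
#' Estimates `S0` and the apparent diffusion coefficient `D` of
#' `S(b) = S0 exp(-b D)` by damped (Levenberg-Marquardt) nonlinear least
#' squares, initialised from a signal-weighted log-linear fit. `D` is
#' constrained to `[0, d_max]`; boundary hits are flagged.
#'
#' @param b_values b-values (s/mm^2); at least two distinct values.
#' @param signals Signal intensities, same length as `b_values`.
#' @param d_max Upper bound on `D` in mm^2/s (default 0.02, far above
#'   free-water diffusivity at body temperature).
#' @param max_iter Iteration cap (default 200).
#' @param tol Relative-cost convergence tolerance (default 1e-10).
#' @return An object of class `adc_fit`: list with `S0`, `D`,
#'   `residual_norm`, `converged`, `clamped`.
#' @examples
#' b <- c(0, 200, 400, 600)
#' fit_monoexp(b, predict_signal(100, 2.11e-3, b))$D
#' @export
fit_monoexp <- function(b_values, signals, d_max = 0.02,
                        max_iter = 200L, tol = 1e-10) {
  if (length(signals) != length(b_values))
    stop("b_values and signals must have equal length", call. = FALSE)
  if (all(signals == 0))
    stop("all-zero signal: nothing to fit", call. = FALSE)
  f <- fit_monoexp_matrix(b_values, matrix(signals, ncol = 1L),
                          d_max = d_max, max_iter = max_iter, tol = tol)
  structure(list(S0 = f$S0[[1L]], D = f$D[[1L]],
                 residual_norm = f$residual_norm[[1L]],
                 converged = f$converged[[1L]],
                 clamped = f$clamped[[1L]]),
            class = "adc_fit")
}

#' @export
print.adc_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential ADC fit: S0 = %.4g, D = %.4g mm^2/s (rss = %.3g%s)\n",
              x$S0, x$D, x$residual_norm^2,
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' Two-pool Gaussian mixture analysis of an ADC distribution
#'
#' Vessel-wall ADC histograms show two populations (a fast pool near the
#' lumen/outer boundary and a slow wall pool). This fits a two-component
#' univariate Gaussian mixture by expectation-maximisation with a
#' deterministic initialisation (split at the median), returning the
#' components ordered fast-first.
#'
#' @param adc_values Finite positive ADC values (mm^2/s); at least 20.
#' @param max_iter EM iteration cap (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-10).
#' @return An object of class `adc_pools`: `mean_fast`, `sd_fast`,
#'   `mean_slow`, `sd_slow`, `weights` (fast, slow; sum 1), `loglik`,
#'   `converged`, `n`.
#' @export
fit_adc_pools <- function(adc_values, max_iter = 500L, tol = 1e-10) {
  x <- as.numeric(adc_values)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("ADC values must be finite and positive", call. = FALSE)
  if (length(x) < 20L)
    stop("at least 20 ADC values are required to identify two pools",
         call. = FALSE)
  fit <- .em_gmm2(x, split = stats::median(x), max_iter = max_iter, tol = tol)
  # order fast (larger mean) first
  ord <- order(fit$mu, decreasing = TRUE)
  structure(list(mean_fast = fit$mu[ord[1L]], sd_fast = fit$sigma[ord[1L]],
                 mean_slow = fit$mu[ord[2L]], sd_slow = fit$sigma[ord[2L]],
                 weights = fit$w[ord], loglik = fit$loglik,
                 converged = fit$converged, n = length(x)),
            class = "adc_pools")
}

# Plain EM for a 2-component univariate Gaussian mixture. Initial means
# come from the two halves of the data around `split`; a variance floor
# guards against degenerate point-mass components collapsing to sd 0.
.em_gmm2 <- function(x, split, max_iter = 500L, tol = 1e-10,
                     mu0 = NULL, w0 = c(0.5, 0.5)) {
  n <- length(x)
  lo <- x <= split
  if (is.null(mu0)) {
    mu <- c(mean(x[!lo]), mean(x[lo]))
    if (any(!is.finite(mu))) mu <- range(x)
  } else mu <- mu0
  sg <- rep(max(stats::sd(x) / 2, diff(range(x)) * 1e-3, 1e-12), 2L)
  w <- w0
  floor_var <- (diff(range(x)) * 1e-6 + 1e-15)^2
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * stats::dnorm(x, mu[1L], sg[1L])
    d2 <- w[2L] * stats::dnorm(x, mu[2L], sg[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g1 <- d1 / tot
    g2 <- 1 - g1
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-10 || n2 < 1e-10) break
    mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
    sg <- sqrt(pmax(c(sum(g1 * (x - mu[1L])^2) / n1,
                      sum(g2 * (x - mu[2L])^2) / n2), floor_var))
    w <- c(n1, n2) / n
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sg, w = w, loglik = ll_old, converged = converged)
}

#' @export
print.adc_pools <- function(x, ...) {
  cat(sprintf(paste0("Two-pool ADC mixture (n = %d):\n",
                     "  fast: %.3g +/- %.3g mm^2/s (weight %.2f)\n",
                     "  slow: %.3g +/- %.3g mm^2/s (weight %.2f)\n"),
              x$n, x$mean_fast, x$sd_fast, x$weights[1L],
              x$mean_slow, x$sd_slow, x$weights[2L]))
  invisible(x)
}

#' Optimal b-value separating two mono-exponential decays
#'
#' The b-value maximising the signal difference
#' `S0 (exp(-b D_slow) - exp(-b D_fast))` between two tissue pools is the
#' closed form `ln(D_fast / D_slow) / (D_fast - D_slow)`, independent of
#' `S0`. In the equal-coefficient limit it tends to `1 / D`.
#'
#' @param D_fast Faster diffusion coefficient (mm^2/s).
#' @param D_slow Slower diffusion coefficient (mm^2/s).
#' @return Optimal b-value (s/mm^2).
#' @examples
#' optimal_bvalue(2.11e-3, 1.27e-3)  # about 605 s/mm^2
#' @export
optimal_bvalue <- function(D_fast, D_slow) {
  if (any(!is.finite(c(D_fast, D_slow))) || D_fast <= 0 || D_slow <= 0)
    stop("diffusion coefficients must be positive", call. = FALSE)
  if (D_fast < D_slow) { tmp <- D_fast; D_fast <- D_slow; D_slow <- tmp }
  if ((D_fast - D_slow) < 1e-12 * D_fast)
    return(1 / D_fast)
  log(D_fast / D_slow) / (D_fast - D_slow)
}
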