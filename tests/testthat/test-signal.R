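test_that("predicted signal follows the mono-exponential decay", {
  expect_equal(predict_signal(100, 1.3e-3, 0), 100)
  expect_equal(predict_signal(0, 1.3e-3, 400), 0)
  expect_equal(predict_signal(100, 2.11e-3, 605), 100 * exp(-605 * 2.11e-3))
  expect_equal(round(predict_signal(100, 2.11e-3, 605), 1), 27.9)
  # strictly decreasing in b for D > 0
  s <- predict_signal(100, 1e-3, seq(0, 1000, 50))
  expect_true(all(diff(s) < 0))
  expect_error(predict_signal(100, 1e-3, -5), "nonnegative")
})

test_that("noiseless signals are inverted to the generating parameters", {
  b <- c(0, 200, 400, 600)
  f <- fit_monoexp(b, predict_signal(100, 2.11e-3, b))
  expect_equal(f$S0, 100, tolerance = 1e-9)
  expect_equal(f$D, 2.11e-3, tolerance = 1e-9)
  expect_true(f$converged)
  expect_false(f$clamped)

  # parameter recovery across a range of coefficients
  for (D in c(1e-4, 8e-4, 1.27e-3, 3e-3)) {
    f <- fit_monoexp(b, predict_signal(42, D, b))
    expect_equal(f$D, D, tolerance = 1e-9)
    expect_equal(f$S0, 42, tolerance = 1e-9)
  }
})

test_that("degenerate signal series are handled explicitly", {
  b <- c(0, 200, 400, 600)
  f <- fit_monoexp(b, c(100, 100, 100, 100))
  expect_equal(f$D, 0)
  expect_equal(f$S0, 100, tolerance = 1e-12)
  expect_error(fit_monoexp(b, c(0, 0, 0, 0)), "all-zero")
  expect_error(fit_monoexp(c(300, 300), c(50, 50)), "distinct b-values")
})

test_that("noisy fits agree with independent oracles", {
  b <- c(0, 200, 400, 600)
  set.seed(21)
  s_true <- predict_signal(100, 1.4e-3, b)
  for (i in 1:10) {
    s <- s_true + rnorm(4, 0, 1)
    f <- fit_monoexp(b, pmax(s, 0))
    # log-linear weighted least squares oracle
    w <- s^2
    cf <- stats::lm(log(s) ~ b, weights = w)$coefficients
    expect_equal(f$D, unname(-cf[2]), tolerance = 0.05)
    # established Levenberg-Marquardt implementation as cross-check
    nls <- minpack.lm::nls.lm(par = list(S0 = max(s), D = 1e-3),
                              fn = function(p) s - p$S0 * exp(-b * p$D))
    expect_equal(f$D, nls$par$D, tolerance = 1e-6)
    expect_equal(f$S0, nls$par$S0, tolerance = 1e-5)
  }
})

test_that("two-pool mixture separates point masses exactly", {
  x <- c(rep(1e-3, 1000), rep(2e-3, 1000))
  p <- fit_adc_pools(x)
  expect_equal(p$mean_fast, 2e-3, tolerance = 1e-9)
  expect_equal(p$mean_slow, 1e-3, tolerance = 1e-9)
  expect_equal(sum(p$weights), 1, tolerance = 1e-9)
  expect_equal(p$weights[1], 0.5, tolerance = 1e-6)
})

test_that("two-pool mixture recovers generating pool means", {
  set.seed(5)
  x <- c(rnorm(1000, 2.11e-3, 0.23e-3), rnorm(1000, 1.27e-3, 0.29e-3))
  x <- x[x > 0]
  p <- fit_adc_pools(x)
  expect_equal(p$mean_fast, 2.11e-3, tolerance = 0.05)
  expect_equal(p$mean_slow, 1.27e-3, tolerance = 0.05)
  expect_true(p$mean_fast > p$mean_slow)
  expect_gt(min(p$weights), 0)
  # independent mixture-model implementation as cross-check
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(c(p$mean_slow, p$mean_fast)),
               sort(unname(mc$parameters$mean)), tolerance = 0.02)
  expect_error(fit_adc_pools(x[1:10]), "at least 20")
  expect_error(fit_adc_pools(c(x, -1e-3)), "positive")
})

test_that("median-split EM attains the likelihood of random restarts", {
  set.seed(9)
  x <- c(rnorm(700, 2.11e-3, 0.23e-3), rnorm(1300, 1.27e-3, 0.29e-3))
  x <- x[x > 0]
  p <- fit_adc_pools(x)
  lls <- replicate(50, {
    mu0 <- sort(sample(x, 2))
    vwdti:::.em_gmm2(x, split = stats::median(x), mu0 = rev(mu0))$loglik
  })
  expect_gte(p$loglik, max(lls) - 1e-6)
})

test_that("pool-mean recovery improves with sample size", {
  err_at <- function(n, seed) {
    set.seed(seed)
    x <- c(rnorm(n / 2, 2.11e-3, 0.23e-3), rnorm(n / 2, 1.27e-3, 0.29e-3))
    p <- fit_adc_pools(x[x > 0])
    abs(p$mean_fast - 2.11e-3) / 2.11e-3 + abs(p$mean_slow - 1.27e-3) / 1.27e-3
  }
  e200 <- mean(vapply(1:5, function(s) err_at(200, s), numeric(1)))
  e20000 <- mean(vapply(1:5, function(s) err_at(20000, s), numeric(1)))
  expect_lt(e20000, e200)
  expect_lt(e20000, 0.05)
})

test_that("optimal b-value matches the closed form and a grid search", {
  b <- optimal_bvalue(2.11e-3, 1.27e-3)
  expect_equal(b, log(2.11 / 1.27) / (2.11e-3 - 1.27e-3), tolerance = 1e-12)
  # brute-force argmax oracle on a fine grid
  grid <- seq(0, 2000, by = 0.01)
  gap <- exp(-grid * 1.27e-3) - exp(-grid * 2.11e-3)
  expect_lt(abs(b - grid[which.max(gap)]), 0.01 + 1e-9)
  # equal-coefficient limit is 1/D
  expect_equal(optimal_bvalue(1e-3, 1e-3), 1000)
  expect_equal(optimal_bvalue(1e-3 + 1e-16, 1e-3), 1000, tolerance = 1e-6)
  # symmetric under exchanging the pool labels
  expect_equal(optimal_bvalue(1.27e-3, 2.11e-3), b)
  expect_error(optimal_bvalue(-1e-3, 1e-3), "positive")
})
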