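#' Region-of-interest summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient
#' of variation (CV, in percent) of a set of values — the summary used
#' for repeated FA measurements of the same vessel wall.
#'
#' @param values At least two finite numeric values.
#' @return An object of class `roi_stats`: `mean`, `sd`, `n`, `cv`
#'   (percent; `NA` with a warning-free flag when the mean is zero).
#' @examples
#' roi_summary(c(0.525, 0.562, 0.563, 0.597))
#' @export
roi_summary <- function(values) {
  x <- as.numeric(values)
  x <- x[is.finite(x)]
  if (length(x) < 2L)
    stop("at least 2 finite values are required", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  structure(list(mean = m, sd = s, n = length(x),
                 cv = if (m == 0) NA_real_ else 100 * s / m,
                 cv_defined = m != 0),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI summary (n = %d): mean = %.4g, sd = %.4g, CV = %s\n",
              x$n, x$mean, x$sd,
              if (x$cv_defined) sprintf("%.2f%%", x$cv) else "undefined"))
  invisible(x)
}

#' Simple linear regression with confidence and prediction bands
#'
#' Ordinary least squares of `y` on `x` with the summaries used for
#' DTI-metric-versus-age analyses: slope, intercept, R^2, adjusted R^2,
#' the F test for the model (for a single predictor, identical to the
#' two-sided t test of the slope), and pointwise 95% confidence and
#' prediction bands over a grid of `x`.
#'
#' @param x,y Paired numeric vectors, n >= 3, `x` not constant.
#' @param level Band coverage (default 0.95).
#' @param band_n Number of grid points for the bands (default 100).
#' @return An object of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `f_statistic`, `p_value`, `n`,
#'   `sigma` (residual SE), `bands` (data frame: `x`, `fit`, `ci_lower`,
#'   `ci_upper`, `pi_lower`, `pi_upper`) and the underlying `lm` object
#'   as `model`.
#' @export
ols_fit <- function(x, y, level = 0.95, band_n = 100L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("x is constant: the regression design is degenerate", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[[1L]], fstat[[2L]], fstat[[3L]], lower.tail = FALSE)
  grid <- data.frame(x = seq(min(x), max(x), length.out = band_n))
  ci <- stats::predict(fit, grid, interval = "confidence", level = level)
  pi <- stats::predict(fit, grid, interval = "prediction", level = level)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = unname(fstat[[1L]]),
                 p_value = unname(p),
                 n = length(x), sigma = sm$sigma, level = level,
                 bands = data.frame(x = grid$x, fit = ci[, "fit"],
                                    ci_lower = ci[, "lwr"],
                                    ci_upper = ci[, "upr"],
                                    pi_lower = pi[, "lwr"],
                                    pi_upper = pi[, "upr"]),
                 model = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(paste0("Linear regression (n = %d): y = %.4gx + %.4g\n",
                     "  R^2 = %.3f (adjusted %.3f), F = %.3f, p = %.4g\n"),
              x$n, x$slope, x$intercept, x$r_squared, x$adj_r_squared,
              x$f_statistic, x$p_value))
  invisible(x)
}

#' Plot a regression fit with its confidence and prediction bands
#'
#' @param x A `regression_fit`.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::plot].
#' @return Invisibly, `x`.
#' @export
plot.regression_fit <- function(x, xlab = "x", ylab = "y", ...) {
  b <- x$bands
  dat <- x$model$model
  graphics::plot(dat$x, dat$y, xlab = xlab, ylab = ylab,
                 ylim = range(b$pi_lower, b$pi_upper, dat$y), pch = 19, ...)
  graphics::lines(b$x, b$fit, lwd = 2)
  graphics::lines(b$x, b$ci_lower, lty = 2, col = "red")
  graphics::lines(b$x, b$ci_upper, lty = 2, col = "red")
  graphics::lines(b$x, b$pi_lower, lty = 3, col = "darkgreen")
  graphics::lines(b$x, b$pi_upper, lty = 3, col = "darkgreen")
  invisible(x)
}
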