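#' Standard ellipse of a bivariate isotope sample
#'
#' The standard ellipse is the 1-sigma contour of a bivariate sample: it is
#' centred on the mean, its semi-axes are the square roots of the
#' eigenvalues of the sample covariance matrix (n-1 denominator), and it
#' contains about 40% of bivariate-normal data (exactly
#' `1 - exp(-1/2) = 0.3935` in the Gaussian limit). The orientation
#' `theta` of the semi-major axis versus the positive x axis is
#' `0.5 * atan2(2 * cov, var_x - var_y)`, mapped into `[0, pi)`; for a
#' perfectly circular cloud (equal variances, zero correlation) the
#' orientation is undefined and reported as 0. The sample-size-corrected
#' ellipse area is `pi * a * b * (n - 1) / (n - 2)`.
#'
#' The slope of the major axis is `tan(theta)` but is computed as
#' `(lambda1 - var_x) / cov` when the covariance is non-zero, which avoids
#' tangent blow-up for near-vertical ellipses.
#'
#' @param x,y paired per-mil samples (at least 3 points, non-zero variance
#'   in at least one coordinate).
#' @return an object of class `n2o_ellipse`: a list with `n`, `mean_x`,
#'   `mean_y`, `sd_x`, `sd_y`, `r`, semi-axes `a >= b`, `theta` (radians in
#'   `[0, pi)`), `slope`, `area_c`, and a `degenerate` flag (`TRUE` for
#'   exactly collinear input, where `b = 0` and `area_c = 0`).
#' @seealso [ellipse_from_stats()] to build the same summary from printed
#'   moments, [containment_fraction()], [tangency_points()].
#' @export
standard_ellipse <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("insufficient points: standard ellipse needs n >= 3")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 && sy == 0) stop("zero variance in both coordinates")
  cv <- stats::cov(x, y)
  r <- if (sx > 0 && sy > 0) cv / (sx * sy) else 0
  ellipse_from_stats(mean(x), mean(y), sx, sy, r, n)
}

#' Standard-ellipse summary from printed bivariate moments
#'
#' Builds the same summary as [standard_ellipse()] directly from the sample
#' mean, standard deviations, correlation and size — the form in which
#' compiled category statistics are tabulated.
#'
#' @param mean_x,mean_y sample means, per-mil.
#' @param sd_x,sd_y sample standard deviations (n-1 denominator), per-mil.
#' @param r Pearson correlation in `[-1, 1]`.
#' @param n sample size (>= 3).
#' @return an `n2o_ellipse`; see [standard_ellipse()].
#' @export
ellipse_from_stats <- function(mean_x, mean_y, sd_x, sd_y, r, n) {
  stopifnot(n >= 3, sd_x >= 0, sd_y >= 0, abs(r) <= 1)
  cv <- r * sd_x * sd_y
  S <- matrix(c(sd_x^2, cv, cv, sd_y^2), 2, 2)
  ev <- eigen(S, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)        # clip tiny negative round-off
  a <- sqrt(lambda[1])
  b <- sqrt(lambda[2])
  degenerate <- lambda[2] <= lambda[1] * 1e-12
  if (degenerate) b <- 0

  if (cv == 0 && sd_x == sd_y) {
    theta <- 0                         # circular cloud: orientation undefined
  } else {
    theta <- 0.5 * atan2(2 * cv, sd_x^2 - sd_y^2)
    if (theta < 0) theta <- theta + pi
  }
  slope <- if (cv != 0) (lambda[1] - sd_x^2) / cv else tan(theta)

  area_c <- if (degenerate) 0 else pi * a * b * (n - 1) / (n - 2)
  structure(
    list(n = n, mean_x = mean_x, mean_y = mean_y, sd_x = sd_x, sd_y = sd_y,
         r = r, a = a, b = b, theta = theta, slope = slope, area_c = area_c,
         degenerate = degenerate),
    class = "n2o_ellipse")
}

#' @export
print.n2o_ellipse <- function(x, digits = 4, ...) {
  cat("Standard ellipse (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  centre     (%.*g, %.*g)\n", digits, x$mean_x, digits, x$mean_y))
  cat(sprintf("  sigma      (%.*g, %.*g), r = %.*g\n",
              digits, x$sd_x, digits, x$sd_y, digits, x$r))
  cat(sprintf("  semi-axes  a = %.*g, b = %.*g, theta = %.*g rad, slope = %.*g\n",
              digits, x$a, digits, x$b, digits, x$theta, digits, x$slope))
  cat(sprintf("  corrected ellipse area = %.*g\n", digits, x$area_c))
  if (x$degenerate) cat("  [degenerate: collinear input]\n")
  invisible(x)
}

ellipse_cov <- function(e) {
  cv <- e$r * e$sd_x * e$sd_y
  matrix(c(e$sd_x^2, cv, cv, e$sd_y^2), 2, 2)
}

#' Fraction of points inside a standard ellipse
#'
#' A point is inside when its squared Mahalanobis distance from the ellipse
#' centre, under the ellipse's covariance, is at most 1. For large
#' bivariate-normal samples evaluated against their own standard ellipse
#' this fraction converges to `1 - exp(-1/2)`, about 39.4% — the "standard
#' ellipse contains ~40% of the data" property.
#'
#' @param x,y paired coordinates.
#' @param ellipse a non-degenerate `n2o_ellipse`.
#' @return fraction in `[0, 1]`.
#' @export
containment_fraction <- function(x, y, ellipse) {
  stopifnot(inherits(ellipse, "n2o_ellipse"))
  if (ellipse$degenerate) stop("degenerate ellipse: containment undefined")
  d2 <- stats::mahalanobis(cbind(x, y),
                           c(ellipse$mean_x, ellipse$mean_y),
                           ellipse_cov(ellipse))
  mean(d2 <= 1)
}

#' Tangency points of the axis-parallel tangent lines
#'
#' The vertical tangent lines touch the standard ellipse at
#' `(mean_x +- sd_x, mean_y +- r * sd_y)` and the horizontal ones at
#' `(mean_x +- r * sd_x, mean_y +- sd_y)`; these are also the points where
#' the two regression lines (y on x, x on y) cross the ellipse boundary.
#'
#' @param ellipse a non-degenerate `n2o_ellipse`.
#' @return a 4 x 2 matrix of (x, y) tangency points, rows named
#'   `vertical+`, `vertical-`, `horizontal+`, `horizontal-`.
#' @export
tangency_points <- function(ellipse) {
  stopifnot(inherits(ellipse, "n2o_ellipse"))
  if (ellipse$degenerate) stop("degenerate ellipse: tangency undefined")
  with(ellipse, matrix(
    c(mean_x + sd_x,     mean_y + r * sd_y,
      mean_x - sd_x,     mean_y - r * sd_y,
      mean_x + r * sd_x, mean_y + sd_y,
      mean_x - r * sd_x, mean_y - sd_y),
    ncol = 2, byrow = TRUE,
    dimnames = list(c("vertical+", "vertical-", "horizontal+", "horizontal-"),
                    c("x", "y"))))
}

#' Boundary of a standard ellipse, for plotting
#'
#' @param ellipse an `n2o_ellipse`.
#' @param n_points number of boundary points.
#' @return a matrix of (x, y) boundary coordinates.
#' @export
ellipse_boundary <- function(ellipse, n_points = 200) {
  t <- seq(0, 2 * pi, length.out = n_points)
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  cbind(x = ellipse$mean_x + ellipse$a * cos(t) * ct - ellipse$b * sin(t) * st,
        y = ellipse$mean_y + ellipse$a * cos(t) * st + ellipse$b * sin(t) * ct)
}

#' @export
plot.n2o_ellipse <- function(x, ..., add = FALSE, col = "black") {
  bd <- ellipse_boundary(x)
  if (add) {
    graphics::lines(bd, col = col, ...)
  } else {
    plot(bd, type = "l", col = col, xlab = "d15N (per-mil)",
         ylab = "d18O (per-mil)", ...)
    graphics::points(x$mean_x, x$mean_y, pch = 3, col = col)
  }
  invisible(x)
}

#' Ordinary least squares line
#'
#' Thin wrapper over [stats::lm()] returning the slope, intercept and R
#' squared of the regression of `y` on `x` (used e.g. for the stratospheric
#' Rayleigh-fractionation line in d15N-d18O space).
#'
#' @param x,y samples with `n >= 3` and non-zero variance in `x`.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
ols_line <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with mid-rank ties. The two-sided p-value uses the
#' exact null distribution when `n1 * n2 <= 400` and there are no ties, and
#' a tie-corrected normal approximation (no continuity correction)
#' otherwise.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `U` (for the first sample), `p_value`, and `method`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  has_ties <- any(ties > 1)

  if (!has_ties && n1 * n2 <= 400) {
    # exact null distribution of U (stats::pwilcox enumerates it)
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1                     # all observations identical
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = p, method = method)
}
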