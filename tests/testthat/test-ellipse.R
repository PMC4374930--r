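test_that("semi-axes and orientation agree with a closed-form eigen oracle", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 5))
    y <- 0.5 * x + rnorm(n, sd = runif(1, 0.5, 5))
    e <- standard_ellipse(x, y)
    o <- eigen2x2_oracle(sd(x), sd(y), cor(x, y))
    expect_equal(e$a, o$a, tolerance = 1e-9)
    expect_equal(e$b, o$b, tolerance = 1e-9)
    expect_equal(e$theta, o$theta, tolerance = 1e-9)
    # eigen-solution identities
    expect_equal(e$a^2 + e$b^2, e$sd_x^2 + e$sd_y^2, tolerance = 1e-9)
    expect_equal(e$a^2 * e$b^2, e$sd_x^2 * e$sd_y^2 * (1 - e$r^2),
                 tolerance = 1e-9)
    expect_equal(e$area_c, pi * e$a * e$b * (n - 1) / (n - 2), tolerance = 1e-12)
    expect_gte(e$theta, 0); expect_lt(e$theta, pi)
    expect_equal(e$slope, tan(e$theta), tolerance = 1e-6)
  }
})

test_that("the ellipse is translation invariant and circular clouds report theta 0", {
  set.seed(11)
  x <- rnorm(40); y <- rnorm(40) + 0.7 * x
  e1 <- standard_ellipse(x, y)
  e2 <- standard_ellipse(x + 100, y - 55)
  for (f in c("a", "b", "theta", "slope", "area_c", "sd_x", "sd_y", "r")) {
    expect_equal(e1[[f]], e2[[f]], tolerance = 1e-9)
  }
  # exact circular symmetry via the moment constructor
  ec <- ellipse_from_stats(0, 0, 2.5, 2.5, 0, 30)
  expect_equal(ec$a, 2.5)
  expect_equal(ec$b, 2.5)
  expect_identical(ec$theta, 0)
  expect_equal(ec$area_c, pi * 2.5^2 * 29 / 28)
})

test_that("degenerate and undersized inputs are flagged or refused", {
  x <- 1:5
  e <- standard_ellipse(x, 2 * x + 3)        # exactly collinear
  expect_true(e$degenerate)
  expect_identical(e$b, 0)
  expect_identical(e$area_c, 0)
  expect_error(standard_ellipse(1:2, 2:3), "insufficient")
  expect_error(standard_ellipse(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(containment_fraction(1, 1, e), "degenerate")
  expect_error(tangency_points(e), "degenerate")
})

test_that("the standard ellipse contains about 39.4% of a Gaussian cloud", {
  set.seed(12)
  n <- 2e5
  x <- rnorm(n, 5, 2)
  y <- 3 + 0.8 * x + rnorm(n, 0, 1.5)
  e <- standard_ellipse(x, y)
  expect_equal(containment_fraction(x, y, e), 1 - exp(-0.5), tolerance = 0.01 / 0.3935)
  # trivial bounds
  expect_equal(containment_fraction(rep(e$mean_x, 9), rep(e$mean_y, 9), e), 1.0)
  expect_equal(containment_fraction(e$mean_x + 10 * e$sd_x, e$mean_y, e), 0.0)
})

test_that("tangency points lie on the boundary and on the regression lines", {
  # no correlation: tangency at the axis extremes
  e0 <- ellipse_from_stats(1, 2, 3, 4, 0, 20)
  tp0 <- tangency_points(e0)
  expect_equal(unname(tp0["vertical+", ]), c(1 + 3, 2))
  expect_equal(unname(tp0["horizontal+", ]), c(1, 2 + 4))
  set.seed(13)
  for (i in 1:10) {
    e <- ellipse_from_stats(rnorm(1), rnorm(1), runif(1, 0.5, 3),
                            runif(1, 0.5, 3), runif(1, -0.9, 0.9), 25)
    tp <- tangency_points(e)
    d2 <- stats::mahalanobis(tp, c(e$mean_x, e$mean_y),
                             matrix(c(e$sd_x^2, e$r * e$sd_x * e$sd_y,
                                      e$r * e$sd_x * e$sd_y, e$sd_y^2), 2))
    expect_equal(unname(d2), rep(1, 4), tolerance = 1e-9)
    # vertical tangency points sit on the y-on-x regression line
    slope_yx <- e$r * e$sd_y / e$sd_x
    pred <- e$mean_y + slope_yx * (tp[1:2, "x"] - e$mean_x)
    expect_equal(unname(tp[1:2, "y"]), unname(pred), tolerance = 1e-9)
    # horizontal tangency points sit on the x-on-y regression line
    slope_xy <- e$r * e$sd_x / e$sd_y
    predx <- e$mean_x + slope_xy * (tp[3:4, "y"] - e$mean_y)
    expect_equal(unname(tp[3:4, "x"]), unname(predx), tolerance = 1e-9)
  }
  # near-perfect correlation (the exact r = 1 ellipse is degenerate):
  # all four tangency points become collinear
  e1 <- ellipse_from_stats(0, 0, 2, 3, 1 - 1e-9, 10)
  tp1 <- tangency_points(e1)
  fit <- ols_line(tp1[, "x"], tp1[, "y"])
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("ols_line matches the closed-form normal equations", {
  x <- c(1, 2, 4); y <- c(2, 3, 9)
  fit <- ols_line(x, y)
  # direct normal-equation solution
  beta <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
          (sum(x^2) - length(x) * mean(x)^2)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(fit$slope, beta, tolerance = 1e-12)
  expect_equal(fit$intercept, alpha, tolerance = 1e-12)
  expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)
  # collinear input (lm warns about the perfect fit; the R^2 is still exact)
  expect_equal(suppressWarnings(ols_line(1:5, 2 * (1:5) + 1)$r_squared), 1)
  expect_error(ols_line(rep(1, 4), 1:4), "zero variance")
  expect_error(ols_line(1:2, 1:2), "3 points")
})

test_that("Mann-Whitney U and p-values match exact enumeration and wilcox.test", {
  # identical samples: U = n1 n2 / 2, p ~ 1
  mw <- mann_whitney(1:6, 1:6)
  expect_equal(mw$U, 18)
  expect_gt(mw$p_value, 0.95)
  # fully separated toy: U = 0, exact two-sided p = 2/choose(4,2)... = 1/3
  mw2 <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw2$U, 0)
  expect_equal(mw2$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(mw2$method, "exact")
  # cross-check the exact branch against wilcox.test on random tie-free data
  set.seed(14)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(10, 0.8)
    mwi <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mwi$U, unname(ref$statistic))
    expect_equal(mwi$p_value, ref$p.value, tolerance = 1e-12)
  }
  # tie-corrected normal branch against wilcox.test without continuity correction
  set.seed(15)
  x <- round(rnorm(30, 0, 2)); y <- round(rnorm(35, 1, 2))
  mw3 <- mann_whitney(x, y)
  ref3 <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(mw3$U, unname(ref3$statistic))
  expect_equal(mw3$p_value, ref3$p.value, tolerance = 1e-10)
  expect_match(mw3$method, "tie correction")
})
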