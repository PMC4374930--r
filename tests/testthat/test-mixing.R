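small_settings <- function(seed = 1, chains = 2) {
  mcmc_settings(chain_length = 12000, burn_in = 4000, thinning = 4,
                n_chains = chains, seed = seed)
}

test_that("a mixture sitting on one source's mean is attributed to that source", {
  src <- recovery_sources()
  prob <- mixing_problem(src$means, matrix(0.01, 3, 2),
                         mixture_mean = src$means["soil", ])
  fit <- fit_mixing_model(prob, small_settings(seed = 3))
  expect_gt(coef(fit)[["soil"]], 0.95)
})

test_that("every retained draw lies on the simplex", {
  src <- recovery_sources()
  prob <- mixing_problem(src$means, src$sds, mixture_mean = c(-8, 38))
  fit <- fit_mixing_model(prob, small_settings(seed = 4))
  expect_true(all(fit$draws >= 0 & fit$draws <= 1))
  expect_equal(rowSums(fit$draws), rep(1, nrow(fit$draws)), tolerance = 1e-12)
  expect_equal(nrow(fit$draws), 2 * (12000 - 4000) / 4)
  # deterministic under the master seed
  fit2 <- fit_mixing_model(prob, small_settings(seed = 4))
  expect_identical(fit$draws, fit2$draws)
})

test_that("prior-only sampling reproduces Dirichlet closed-form moments", {
  src <- recovery_sources()
  alpha <- c(1, 1, 1)
  prob <- mixing_problem(src$means, src$sds, mixture_mean = c(-8, 38),
                         prior_alpha = alpha)
  st <- mcmc_settings(chain_length = 34000, burn_in = 4000, thinning = 4,
                      n_chains = 2, seed = 5)
  fit <- fit_mixing_model(prob, st, prior_only = TRUE)
  expect_gte(nrow(fit$draws), 1e4)
  a0 <- sum(alpha)
  for (k in 1:3) {
    expect_equal(mean(fit$draws[, k]), alpha[k] / a0, tolerance = 0.05)
    v <- alpha[k] * (a0 - alpha[k]) / (a0^2 * (a0 + 1))
    expect_equal(var(fit$draws[, k]), v, tolerance = 0.1)
  }
  # marginal of a Dirichlet(1,1,1) component is Beta(1, 2)
  expect_equal(unname(quantile(fit$draws[, 1], 0.025)), qbeta(0.025, 1, 2),
               tolerance = 0.25)
  expect_equal(unname(quantile(fit$draws[, 1], 0.5)), qbeta(0.5, 1, 2),
               tolerance = 0.05)
  # asymmetric prior
  prob2 <- mixing_problem(src$means, src$sds, mixture_mean = c(-8, 38),
                          prior_alpha = c(4, 2, 1))
  fit2 <- fit_mixing_model(prob2, st, prior_only = TRUE)
  expect_equal(unname(colMeans(fit2$draws)), c(4, 2, 1) / 7, tolerance = 0.06)
})

test_that("permuting source labels permutes the posterior summaries", {
  src <- recovery_sources()
  prob <- mixing_problem(src$means, src$sds, mixture_mean = c(-9, 40))
  perm <- c(3, 1, 2)
  prob_p <- mixing_problem(src$means[perm, ], src$sds[perm, ],
                           mixture_mean = c(-9, 40))
  st <- small_settings(seed = 6)
  fit <- fit_mixing_model(prob, st)
  fit_p <- fit_mixing_model(prob_p, st)
  m <- coef(fit)[rownames(src$means)[perm]]
  mp <- coef(fit_p)
  expect_equal(unname(mp), unname(m), tolerance = 0.08)
})

test_that("with two sources and one tracer the posterior concentrates on the
           deterministic mixing solution", {
  mu <- rbind(A = -20, B = 10)
  sds <- matrix(0.05, 2, 1)
  d_mix <- -11   # true p_A = (d_mix - d_B)/(d_A - d_B) = 0.7
  prob <- mixing_problem(mu, sds, mixture_mean = d_mix)
  fit <- fit_mixing_model(prob, small_settings(seed = 7))
  expect_equal(coef(fit)[["A"]], 0.7, tolerance = 0.01)
})

test_that("posterior summaries have the standard layout and sane degenerate limits", {
  draws <- matrix(rep(c(0.5, 0.3, 0.2), each = 200), 200, 3)
  colnames(draws) <- c("soil", "freshwater", "marine")
  s <- summarize_posterior(draws)
  expect_equal(names(s), c("source", "mean", "sd", "q2.5", "q5", "q25",
                           "q50", "q75", "q95", "q97.5"))
  expect_equal(s$sd, rep(0, 3))
  expect_equal(s$q2.5, s$q97.5)
  expect_equal(s$mean, c(0.5, 0.3, 0.2))
  # quantile rows are monotone for a real posterior
  src <- recovery_sources()
  prob <- mixing_problem(src$means, src$sds, mixture_mean = c(-8, 38))
  fit <- fit_mixing_model(prob, small_settings(seed = 8))
  qcols <- as.matrix(fit$summary[, grep("^q", names(fit$summary))])
  expect_true(all(apply(qcols, 1, function(r) all(diff(r) >= 0))))
  expect_error(summarize_posterior(draws[1:50, ]), "100")
})

test_that("problem and settings constructors validate their inputs", {
  src <- recovery_sources()
  expect_error(mixing_problem(src$means[1, , drop = FALSE], src$sds[1, , drop = FALSE],
                              c(0, 0)), "2 sources")
  expect_error(mixing_problem(src$means, src$sds[, 1, drop = FALSE], c(0, 0)),
               "dimension")
  expect_error(mixing_problem(src$means, src$sds, c(0, 0, 0)), "mismatch")
  expect_error(mixing_problem(src$means, src$sds, c(0, 0),
                              prior_alpha = c(1, -1, 1)), "positive")
  expect_error(mcmc_settings(1000, 2000), "burn_in")
  expect_error(mcmc_settings(n_chains = 1), "n_chains")
})

test_that("Gelman-Rubin matches the between/within formula and its limits", {
  # identical chains: exactly 1
  ch <- matrix(rnorm(100), 50, 2)
  ch[, 2] <- ch[, 1]
  expect_identical(gelman_rubin(ch), 1)
  # zero-variance chains: defined as 1
  expect_identical(gelman_rubin(matrix(5, 20, 3)), 1)
  # hand formula on a 10-draw toy with a large offset
  c1 <- c(1.2, 0.8, 1.1, 0.9, 1.0, 1.3, 0.7, 1.05, 0.95, 1.0)
  c2 <- c1 + 10
  W <- (var(c1) + var(c2)) / 2
  B_over_n <- var(c(mean(c1), mean(c2)))
  hand <- sqrt(((10 - 1) / 10 * W + B_over_n) / W)
  expect_equal(gelman_rubin(list(c1, c2)), hand, tolerance = 1e-12)
  expect_gt(gelman_rubin(list(c1, c2)), 10)
  # halves of one long well-mixed run
  set.seed(30)
  long <- as.vector(arima.sim(list(ar = 0.5), 4000))
  expect_lt(gelman_rubin(cbind(long[1:2000], long[2001:4000])), 1.05)
  expect_error(gelman_rubin(matrix(1:10, 10, 1)), "2 chains")
  expect_error(gelman_rubin(matrix(1:8, 4, 2)), "short")
})

test_that("Geweke z-scores separate stationary chains from drifting ones", {
  expect_identical(geweke(rep(3.2, 500)), 0)
  set.seed(31)
  z <- replicate(50, geweke(rnorm(1000)))
  expect_lt(mean(abs(z) > 3), 0.05)            # ~0.3% expected
  drift <- rnorm(1000) + seq(0, 5, length.out = 1000)
  expect_gt(abs(geweke(drift)), 5)
  expect_error(geweke(rnorm(50)), "short")
})

test_that("non-converged chains trigger an R-hat warning, not silence", {
  # a near-degenerate likelihood freezes each chain close to where it
  # started, so between-chain variance dwarfs within-chain variance
  src <- recovery_sources()
  prob <- mixing_problem(src$means, matrix(1e-9, 3, 2),
                         mixture_mean = c(-9.9, 37.4))
  st <- mcmc_settings(chain_length = 400, burn_in = 150, thinning = 1,
                      n_chains = 3, seed = 10)
  expect_warning(fit_mixing_model(prob, st), "R-hat")
  set.seed(32)
  expect_gt(gelman_rubin(list(rnorm(100, 0, 0.01), rnorm(100, 1, 0.01))), 1.1)
})
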