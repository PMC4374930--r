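#' Define an isotope mixing problem
#'
#' A mixture (e.g. the flux-weighted global mean N2O source) is modelled as
#' a convex combination of source endmembers on 2 or 3 isotope tracers
#' (d15N_bulk, d18O, optionally SP):
#' `delta_mix_j ~ Normal(sum_k p_k mu_kj, sqrt(sum_k p_k^2 sigma_kj^2 + mix_sd_j^2))`
#' with proportions `p ~ Dirichlet(alpha)` on the simplex. This is the
#' fully-specified (weighted-variance) mixing likelihood; hierarchical
#' process/residual error structures are deliberately not modelled.
#'
#' @param source_means K x J matrix of per-source tracer means (rows named
#'   by source, e.g. soil/freshwater/marine).
#' @param source_sds K x J matrix of per-source tracer standard deviations.
#' @param mixture_mean length-J vector of mixture tracer values.
#' @param mixture_sd length-J vector of mixture uncertainties (may be 0).
#' @param prior_alpha Dirichlet concentration per source (default all 1,
#'   the uniform prior on the simplex).
#' @return a list of class `n2o_mixproblem`.
#' @seealso [mixing_sources_from_data()] to derive `source_means`/`source_sds`
#'   from a filtered dataset; [fit_mixing_model()].
#' @export
mixing_problem <- function(source_means, source_sds, mixture_mean,
                           mixture_sd = NULL, prior_alpha = NULL) {
  source_means <- as.matrix(source_means)
  source_sds <- as.matrix(source_sds)
  K <- nrow(source_means); J <- ncol(source_means)
  if (K < 2) stop("need at least 2 sources")
  if (!(J %in% c(2, 3)) && J != 1) stop("tracer count must be 1, 2 or 3")
  if (!all(dim(source_sds) == c(K, J))) stop("source_sds dimension mismatch")
  if (length(mixture_mean) != J) stop("mixture tracer count mismatch")
  if (is.null(mixture_sd)) mixture_sd <- rep(0, J)
  if (length(mixture_sd) != J) stop("mixture_sd length mismatch")
  if (is.null(prior_alpha)) prior_alpha <- rep(1, K)
  if (length(prior_alpha) != K || any(prior_alpha <= 0)) {
    stop("prior_alpha must be positive, one per source")
  }
  if (any(source_sds < 0) || any(mixture_sd < 0)) stop("negative SD")
  if (is.null(rownames(source_means))) {
    rownames(source_means) <- paste0("source", seq_len(K))
  }
  structure(list(source_names = rownames(source_means),
                 source_means = source_means, source_sds = source_sds,
                 mixture_mean = as.numeric(mixture_mean),
                 mixture_sd = as.numeric(mixture_sd),
                 prior_alpha = prior_alpha,
                 n_tracers = J),
            class = "n2o_mixproblem")
}

#' Per-source tracer statistics from a filtered dataset
#'
#' Computes the mean and standard deviation of each tracer for each source
#' category, the form consumed by [mixing_problem()].
#'
#' @param dataset an [n2o_dataset()], normally the output of
#'   [filter_source_subset()].
#' @param sources category labels to use as sources.
#' @param tracers dataset columns to use as tracers.
#' @return list with `means` and `sds` matrices (sources x tracers).
#' @export
mixing_sources_from_data <- function(dataset,
                                     sources = c("soil", "freshwater", "marine"),
                                     tracers = c("d15N_bulk", "d18O")) {
  stopifnot(inherits(dataset, "n2o_dataset"))
  means <- sds <- matrix(NA_real_, length(sources), length(tracers),
                         dimnames = list(sources, tracers))
  for (s in sources) {
    sub <- dataset[dataset$category == s, tracers, drop = FALSE]
    means[s, ] <- vapply(sub, mean, numeric(1), na.rm = TRUE)
    sds[s, ] <- vapply(sub, stats::sd, numeric(1), na.rm = TRUE)
  }
  list(means = means, sds = sds)
}

#' MCMC settings for the mixing model
#'
#' Defaults mirror the settings found adequate by Gelman-Rubin and Geweke
#' diagnostics for this class of problem: chain length 300,000, burn-in
#' 200,000, thinning 50 for 2-tracer runs or 100 for 3-tracer runs, and 3
#' chains. Scaled-down settings are appropriate for tests and quick looks.
#'
#' @param chain_length total iterations per chain.
#' @param burn_in iterations discarded (must be < `chain_length`).
#' @param thinning keep every `thinning`-th post-burn-in draw; if `NULL`,
#'   chosen by tracer count at fit time (50 for 2 tracers, 100 for 3).
#' @param n_chains number of chains (>= 2 so R-hat is defined).
#' @param seed master seed; per-chain streams are spawned from it.
#' @return a list of class `n2o_mcmc_settings`.
#' @export
mcmc_settings <- function(chain_length = 300000, burn_in = 200000,
                          thinning = NULL, n_chains = 3, seed = 1) {
  stopifnot(burn_in < chain_length, is.null(thinning) || thinning >= 1,
            n_chains >= 2)
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 thinning = if (is.null(thinning)) NULL else as.integer(thinning),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "n2o_mcmc_settings")
}

# log target density on the unconstrained (softmax) scale:
# log Dirichlet(p; alpha) + log |d p / d z| = sum(alpha_k * log p_k) + const.
# prior_only drops the likelihood (used for sampler validation: the draws
# must then reproduce Dirichlet(alpha) exactly in distribution).
mix_log_target <- function(z, problem, prior_only = FALSE) {
  K <- length(problem$prior_alpha)
  ez <- exp(c(z, 0) - max(c(z, 0)))
  p <- ez / sum(ez)
  if (any(p <= 0)) return(-Inf)
  lt <- sum(problem$prior_alpha * log(p))
  if (!prior_only) {
    mu <- colSums(p * problem$source_means)
    sd <- sqrt(colSums(p^2 * problem$source_sds^2) + problem$mixture_sd^2)
    if (any(sd <= 0)) {
      # exact-match degenerate likelihood: -Inf unless means coincide
      if (any(abs(problem$mixture_mean - mu)[sd <= 0] > 0)) return(-Inf)
      sd[sd <= 0] <- .Machine$double.eps
    }
    lt <- lt + sum(stats::dnorm(problem$mixture_mean, mu, sd, log = TRUE))
  }
  if (!is.finite(lt)) return(-Inf)
  lt
}

softmax_p <- function(z) {
  ez <- exp(c(z, 0) - max(c(z, 0)))
  ez / sum(ez)
}

# one adaptive random-walk Metropolis chain in the (K-1)-dim softmax space.
# Proposal increments and acceptance uniforms are pre-generated (scaled by
# the current step size), which keeps the iteration loop lean.
run_mix_chain <- function(problem, chain_length, burn_in, thinning, seed,
                          prior_only = FALSE) {
  set.seed(seed)
  K <- length(problem$prior_alpha)
  d <- K - 1
  alpha <- problem$prior_alpha
  mu_s <- problem$source_means
  var_s <- problem$source_sds^2
  mix <- problem$mixture_mean
  mix_var <- problem$mixture_sd^2

  log_target <- function(z) {
    zz <- c(z, 0)
    ez <- exp(zz - max(zz))
    p <- ez / sum(ez)
    lt <- sum(alpha * log(p))
    if (!prior_only) {
      m <- colSums(p * mu_s)
      v <- colSums(p^2 * var_s) + mix_var
      if (any(v <= 0)) {
        if (any(abs(mix - m)[v <= 0] > 0)) return(-Inf)
        v[v <= 0] <- .Machine$double.eps
      }
      lt <- lt - 0.5 * sum((mix - m)^2 / v + log(v))
    }
    if (!is.finite(lt)) return(-Inf)
    lt
  }

  z <- stats::rnorm(d, 0, 0.5)       # dispersed start
  incr <- matrix(stats::rnorm(chain_length * d), chain_length, d)
  logu <- log(stats::runif(chain_length))
  lt <- log_target(z)
  step <- 0.5
  keep_idx <- seq.int(burn_in + thinning, chain_length, by = thinning)
  draws <- matrix(NA_real_, length(keep_idx), K)
  ki <- 1L
  n_acc <- 0L; acc_window <- 0L
  for (it in seq_len(chain_length)) {
    zp <- z + step * incr[it, ]
    ltp <- log_target(zp)
    if (logu[it] < ltp - lt) {
      z <- zp; lt <- ltp
      acc_window <- acc_window + 1L
      if (it > burn_in) n_acc <- n_acc + 1L
    }
    # adapt the proposal scale toward ~30% acceptance during burn-in only
    if (it <= burn_in && it %% 100L == 0L) {
      step <- step * exp(acc_window / 100 - 0.3)
      acc_window <- 0L
    }
    if (ki <= length(keep_idx) && it == keep_idx[ki]) {
      draws[ki, ] <- softmax_p(z)
      ki <- ki + 1L
    }
  }
  list(draws = draws, acceptance = n_acc / max(1L, chain_length - burn_in),
       step = step)
}

#' Fit the Dirichlet-prior Bayesian isotope mixing model
#'
#' Samples the posterior of the source proportions `p` on the simplex by
#' adaptive random-walk Metropolis in softmax-transformed coordinates
#' (the proposal scale is tuned toward ~30% acceptance during burn-in and
#' then frozen, so the retained draws come from a fixed-kernel chain). The
#' fit is deterministic for a fixed master seed: per-chain seeds are
#' spawned from it.
#'
#' Convergence is reported per source proportion: Gelman-Rubin R-hat across
#' chains and the Geweke z score per chain. R-hat above 1.1 triggers a
#' warning, never a silent result.
#'
#' @param problem an [mixing_problem()].
#' @param settings an [mcmc_settings()].
#' @param prior_only if `TRUE`, ignore the likelihood and sample the
#'   Dirichlet prior (sampler validation).
#' @return an object of class `n2o_mixfit`: retained draws (rows sum to 1),
#'   chain ids, per-source summary (mean, sd, quantiles at 2.5/5/25/50/75/
#'   95/97.5%), diagnostics (`rhat`, `geweke` matrix, acceptance rates),
#'   the problem and settings.
#' @export
fit_mixing_model <- function(problem, settings = mcmc_settings(),
                             prior_only = FALSE) {
  stopifnot(inherits(problem, "n2o_mixproblem"),
            inherits(settings, "n2o_mcmc_settings"))
  thinning <- settings$thinning
  if (is.null(thinning)) thinning <- if (problem$n_tracers >= 3) 100L else 50L
  set.seed(settings$seed)
  chain_seeds <- sample.int(.Machine$integer.max, settings$n_chains)

  chains <- lapply(seq_len(settings$n_chains), function(i) {
    run_mix_chain(problem, settings$chain_length, settings$burn_in,
                  thinning, chain_seeds[i], prior_only)
  })
  per_chain <- lapply(chains, `[[`, "draws")
  draws <- do.call(rbind, per_chain)
  colnames(draws) <- problem$source_names
  chain_id <- rep(seq_along(per_chain), vapply(per_chain, nrow, 1L))

  K <- length(problem$source_names)
  rhat <- vapply(seq_len(K), function(k) {
    gelman_rubin(vapply(per_chain, function(m) m[, k],
                        numeric(nrow(per_chain[[1]]))))
  }, numeric(1))
  gw <- vapply(seq_len(K), function(k) {
    vapply(per_chain, function(m) {
      if (nrow(m) >= 100) geweke(m[, k]) else NA_real_
    }, numeric(1))
  }, numeric(length(per_chain)))
  gw <- matrix(gw, nrow = settings$n_chains,
               dimnames = list(NULL, problem$source_names))
  names(rhat) <- problem$source_names
  if (any(rhat > 1.1)) {
    warning("R-hat > 1.1 for: ",
            paste(names(rhat)[rhat > 1.1], collapse = ", "),
            " - chains may not have converged")
  }

  fit <- structure(
    list(draws = draws, chain_id = chain_id,
         acceptance = vapply(chains, `[[`, numeric(1), "acceptance"),
         rhat = rhat, geweke = gw,
         problem = problem, settings = settings,
         thinning = thinning, prior_only = prior_only),
    class = "n2o_mixfit")
  fit$summary <- summarize_posterior(fit)
  fit
}

#' Summarize a mixing-model posterior
#'
#' Emits the standard mixing-model summary layout: per-source mean
#' contribution, standard deviation, and the 2.5/5/25/50/75/95/97.5%
#' quantiles of the posterior proportion.
#'
#' @param fit an `n2o_mixfit`, or a draws matrix with >= 100 rows.
#' @return data frame, one row per source.
#' @export
summarize_posterior <- function(fit) {
  draws <- if (inherits(fit, "n2o_mixfit")) fit$draws else as.matrix(fit)
  if (nrow(draws) < 100) stop("need at least 100 retained draws")
  probs <- c(0.025, 0.05, 0.25, 0.5, 0.75, 0.95, 0.975)
  out <- data.frame(
    source = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    row.names = NULL)
  qs <- t(apply(draws, 2, stats::quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  cbind(out, as.data.frame(qs, row.names = seq_len(nrow(out))))
}

#' @export
print.n2o_mixfit <- function(x, digits = 3, ...) {
  cat("Bayesian isotope mixing model (", x$problem$n_tracers, " tracers, ",
      length(x$problem$source_names), " sources",
      if (x$prior_only) ", prior only" else "", ")\n", sep = "")
  cat("  ", nrow(x$draws), " retained draws (",
      x$settings$n_chains, " chains, thinning ", x$thinning, ")\n", sep = "")
  tab <- cbind(round(x$summary[, c("mean", "sd", "q2.5", "q50", "q97.5")],
                     digits),
               rhat = round(x$rhat, 3))
  rownames(tab) <- x$summary$source
  print(tab)
  invisible(x)
}

#' @export
summary.n2o_mixfit <- function(object, ...) object$summary

#' @export
coef.n2o_mixfit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$source)
}

#' @export
plot.n2o_mixfit <- function(x, ...) {
  K <- ncol(x$draws)
  op <- graphics::par(mfrow = c(1, K))
  on.exit(graphics::par(op))
  for (k in seq_len(K)) {
    plot(stats::density(x$draws[, k], from = 0, to = 1),
         main = colnames(x$draws)[k], xlab = "proportion", ...)
  }
  invisible(x)
}
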