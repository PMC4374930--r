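#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance diagnostic for one scalar
#' parameter: with `m` chains of length `n`, `W` the mean within-chain
#' variance and `B/n` the variance of the chain means, the PSRF is
#' `sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate the chains are
#' sampling the same distribution. Because `B = 0` for identical chains
#' drives the raw formula slightly below 1, the result is floored at 1;
#' degenerate (zero within-variance) chains are defined as 1.
#'
#' @param chains a matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least 2 chains of length >= 10.
#' @return the R-hat estimate (>= 1).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1) stop("chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("chains too short (need length >= 10)")
  W <- mean(apply(chains, 2, stats::var))
  if (W == 0) return(1)
  B_over_n <- stats::var(colMeans(chains))
  max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
}

# spectral density of a chain at frequency zero, via an AIC-selected AR fit
spectrum0_ar <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  ord_max <- min(30L, max(1L, floor(10 * log10(n))))
  fit <- tryCatch(stats::ar(x, aic = TRUE, order.max = ord_max),
                  error = function(e) NULL)
  if (is.null(fit) || fit$order == 0) return(stats::var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window of the chain with the mean of a
#' late window: `z = (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)`, where the
#' standard errors use the estimated spectral density at frequency zero (an
#' AR-fit estimate), so autocorrelation within each window is accounted
#' for. For a stationary, well-mixed chain `z` is asymptotically standard
#' normal.
#'
#' @param chain numeric vector of at least 100 draws.
#' @param frac_a fraction of the chain in the early window (default 0.1).
#' @param frac_b fraction in the late window (default 0.5).
#' @return the z score (0 for a constant chain).
#' @export
geweke <- function(chain, frac_a = 0.1, frac_b = 0.5) {
  n <- length(chain)
  if (n < 100) stop("chain too short for Geweke diagnostic (need >= 100)")
  stopifnot(frac_a > 0, frac_b > 0, frac_a + frac_b <= 1)
  a <- chain[seq_len(floor(frac_a * n))]
  b <- chain[seq.int(n - floor(frac_b * n) + 1L, n)]
  se2 <- spectrum0_ar(a) / length(a) + spectrum0_ar(b) / length(b)
  if (se2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(se2)
}
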