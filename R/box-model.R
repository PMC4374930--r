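#' Parameters of the two-box tropospheric N2O isotope mass balance
#'
#' The troposphere is treated as one well-mixed box exchanging with the
#' stratosphere, where photochemical destruction of N2O enriches the
#' residual gas (apparent enrichment factor `epsilon`). At quasi-steady
#' state the observed downward trend in the tropospheric delta value
#' constrains the flux-weighted mean delta of all surface sources:
#'
#' `Burden * d(delta_trop)/dt = Sum_Sources * (delta_sources - delta_trop) - epsilon * L`
#'
#' Defaults are the published modern-atmosphere values for the chosen
#' isotope system: tropospheric burden 1553 (+- 21.742) Tg N; tropospheric
#' delta trends -0.035 (+- 0.002) per-mil/yr for 15N and -0.022 (+- 0.004)
#' for 18O; total source 17.9 Tg N/yr (+- 25% relative); stratospheric loss
#' 14.3 Tg N/yr (+- 25% relative); epsilon -14.9 (+- 0.5) per-mil for 15N,
#' -13.5 (+- 0.5) for 18O; tropospheric delta 6.55 (+- 0.47) and 44.40
#' (+- 0.34) per-mil; continental (pooled soil + freshwater) source delta
#' -13.11 (+- 11.51) and 34.32 (+- 10.96); marine source delta 5.14
#' (+- 1.93) and 44.76 (+- 3.62).
#'
#' @param isotope `"15N"` or `"18O"` — selects the default parameter set.
#' @param burden,burden_sd tropospheric N2O burden, Tg N.
#' @param trend,trend_sd tropospheric delta trend, per-mil per year.
#' @param total_source total annual source, Tg N/yr; `total_source_rsd` is
#'   its relative 1-sigma (0.25 = 25%).
#' @param delta_trop,delta_trop_sd modern tropospheric delta, per-mil.
#' @param epsilon,epsilon_sd apparent stratospheric enrichment factor, per-mil.
#' @param loss_rate stratospheric photochemical loss, Tg N/yr;
#'   `loss_rate_rsd` its relative 1-sigma.
#' @param delta_cont,delta_cont_sd continental source delta, per-mil.
#' @param delta_ocean,delta_ocean_sd marine source delta, per-mil.
#' @return a list of class `n2o_boxparams`.
#' @export
box_model_params <- function(isotope = c("15N", "18O"),
                             burden = 1553, burden_sd = 21.742,
                             trend = NULL, trend_sd = NULL,
                             total_source = 17.9, total_source_rsd = 0.25,
                             delta_trop = NULL, delta_trop_sd = NULL,
                             epsilon = NULL, epsilon_sd = NULL,
                             loss_rate = 14.3, loss_rate_rsd = 0.25,
                             delta_cont = NULL, delta_cont_sd = NULL,
                             delta_ocean = NULL, delta_ocean_sd = NULL) {
  isotope <- match.arg(isotope)
  def <- if (isotope == "15N") {
    list(trend = -0.035, trend_sd = 0.002,
         delta_trop = 6.55, delta_trop_sd = 0.47,
         epsilon = -14.9, epsilon_sd = 0.5,
         delta_cont = -13.11, delta_cont_sd = 11.51,
         delta_ocean = 5.14, delta_ocean_sd = 1.93)
  } else {
    list(trend = -0.022, trend_sd = 0.004,
         delta_trop = 44.40, delta_trop_sd = 0.34,
         epsilon = -13.5, epsilon_sd = 0.5,
         delta_cont = 34.32, delta_cont_sd = 10.96,
         delta_ocean = 44.76, delta_ocean_sd = 3.62)
  }
  p <- list(
    isotope = isotope,
    burden = burden, burden_sd = burden_sd,
    trend = if (is.null(trend)) def$trend else trend,
    trend_sd = if (is.null(trend_sd)) def$trend_sd else trend_sd,
    total_source = total_source,
    total_source_sd = total_source * total_source_rsd,
    delta_trop = if (is.null(delta_trop)) def$delta_trop else delta_trop,
    delta_trop_sd = if (is.null(delta_trop_sd)) def$delta_trop_sd else delta_trop_sd,
    epsilon = if (is.null(epsilon)) def$epsilon else epsilon,
    epsilon_sd = if (is.null(epsilon_sd)) def$epsilon_sd else epsilon_sd,
    loss_rate = loss_rate,
    loss_rate_sd = loss_rate * loss_rate_rsd,
    delta_cont = if (is.null(delta_cont)) def$delta_cont else delta_cont,
    delta_cont_sd = if (is.null(delta_cont_sd)) def$delta_cont_sd else delta_cont_sd,
    delta_ocean = if (is.null(delta_ocean)) def$delta_ocean else delta_ocean,
    delta_ocean_sd = if (is.null(delta_ocean_sd)) def$delta_ocean_sd else delta_ocean_sd
  )
  stopifnot(p$total_source > 0, p$loss_rate >= 0, p$burden > 0)
  sds <- unlist(p[grep("_sd$", names(p))])
  if (any(sds < 0)) stop("all parameter standard deviations must be >= 0")
  class(p) <- "n2o_boxparams"
  p
}

#' Flux-weighted global mean source signature
#'
#' Rearranges the tropospheric isotope mass balance to solve for the
#' flux-weighted delta of the average modern N2O source:
#' `(burden * trend + epsilon * loss_rate + total_source * delta_trop) / total_source`.
#' The term `-epsilon * loss_rate` is the net annual isotope flux returned
#' from the stratosphere to the troposphere (per-mil Tg N/yr).
#'
#' @param params an [box_model_params()] object (or one overridden by the
#'   caller). Vectorised over parameter fields, which the Monte-Carlo
#'   propagation exploits.
#' @return per-mil source signature.
#' @export
source_signature <- function(params) {
  if (any(params$total_source == 0)) stop("total_source must be non-zero")
  with(params, (burden * trend + epsilon * loss_rate +
                  total_source * delta_trop) / total_source)
}

#' Ocean/continental partition of the total N2O source
#'
#' Assuming the total source is split between a marine and a continental
#' (soil + freshwater) endmember, the marine flux follows from the mass
#' balance:
#' `F_ocean = (burden * trend + epsilon * L + total_source * (delta_trop - delta_cont)) / (delta_ocean - delta_cont)`,
#' with `F_cont = total_source - F_ocean`.
#'
#' @inheritParams source_signature
#' @return list of class `n2o_boxmodel` with `delta_sources`, `f_ocean`,
#'   `f_cont` (Tg N/yr), `ocean_fraction`, `cont_fraction`,
#'   `net_isotope_flux` (= `-epsilon * loss_rate`, per-mil Tg N/yr), and the
#'   parameters used.
#' @export
ocean_flux <- function(params) {
  denom <- params$delta_ocean - params$delta_cont
  if (any(denom == 0)) {
    stop("sources isotopically indistinguishable: delta_ocean = delta_cont")
  }
  num <- with(params, burden * trend + epsilon * loss_rate +
                total_source * (delta_trop - delta_cont))
  f_ocean <- num / denom
  f_cont <- params$total_source - f_ocean
  structure(
    list(isotope = params$isotope,
         delta_sources = source_signature(params),
         f_ocean = f_ocean, f_cont = f_cont,
         ocean_fraction = f_ocean / params$total_source,
         cont_fraction = f_cont / params$total_source,
         net_isotope_flux = -params$epsilon * params$loss_rate,
         params = params),
    class = "n2o_boxmodel")
}

#' @export
print.n2o_boxmodel <- function(x, ...) {
  cat("Two-box N2O isotope mass balance (", x$isotope, ")\n", sep = "")
  fmt <- function(v, s) {
    if (is.null(s)) sprintf("%.2f", v) else sprintf("%.2f (+- %.2f)", v, s)
  }
  cat("  mean source signature: ",
      fmt(x$delta_sources, x$delta_sources_sd), " per-mil\n", sep = "")
  iv <- function(q) sprintf(", MC 95%% interval [%.1f, %.1f]",
                            q[["2.5%"]], q[["97.5%"]])
  cat("  F_ocean: ", sprintf("%.2f", x$f_ocean), " Tg N/yr (",
      sprintf("%.0f%%", 100 * x$ocean_fraction),
      if (!is.null(x$f_ocean_quantiles)) iv(x$f_ocean_quantiles),
      ")\n", sep = "")
  cat("  F_cont:  ", sprintf("%.2f", x$f_cont), " Tg N/yr (",
      sprintf("%.0f%%", 100 * x$cont_fraction),
      if (!is.null(x$f_cont_quantiles)) iv(x$f_cont_quantiles),
      ")\n", sep = "")
  cat("  net isotope flux (-epsilon*L): ",
      sprintf("%.1f", x$net_isotope_flux), " per-mil Tg N/yr\n", sep = "")
  if (!is.null(x$n_draws)) {
    cat("  uncertainties: Monte-Carlo, ", x$n_draws, " draws\n", sep = "")
  }
  invisible(x)
}

#' Loss-rate sensitivity scenario
#'
#' Re-evaluates the flux partition after moving `dL` Tg N/yr from the
#' stratospheric loss rate to the total source (L - dL, total + dL) — the
#' perturbation under which the oxygen-isotope balance turns a negative
#' ocean flux positive.
#'
#' @inheritParams source_signature
#' @param dL Tg N/yr to shift; `loss_rate - dL` must stay non-negative.
#' @return an `n2o_boxmodel`, as [ocean_flux()].
#' @export
sensitivity_scenario <- function(params, dL) {
  if (params$loss_rate - dL < 0) stop("loss_rate - dL must be >= 0")
  p <- params
  p$loss_rate <- p$loss_rate - dL
  p$total_source <- p$total_source + dL
  p$loss_rate_sd <- params$loss_rate_sd / params$loss_rate * p$loss_rate
  p$total_source_sd <- params$total_source_sd / params$total_source * p$total_source
  ocean_flux(p)
}

# strictly positive quantities are drawn lognormal with the requested mean
# and SD. A Gaussian truncated at zero would leave finite density near
# S = 0, making ratios like delta_sources = A/S + delta_trop have infinite
# variance, so their sample SD never stabilises; the lognormal matches the
# first two moments while keeping all ratio moments finite.
rlnorm_match <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Monte-Carlo uncertainty propagation through the mass balance
#'
#' Each uncertain parameter is drawn independently (`n_draws` times):
#' Gaussian for the delta values, trend and enrichment factor; lognormal
#' with matching mean and SD for the strictly positive budget quantities
#' (burden, total source, loss rate), which keeps the moments of the ratio
#' outputs finite. Within one draw the same
#' total-source value enters everywhere it appears (it is physically one
#' quantity). Reported uncertainties are the sample standard deviations of
#' the Monte-Carlo outputs; point estimates remain the deterministic
#' values.
#'
#' @inheritParams source_signature
#' @param n_draws number of Monte-Carlo draws (>= 1000).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param keep_draws if `TRUE`, retain the per-draw outputs in `mc_draws`.
#' @return an `n2o_boxmodel` with added `delta_sources_sd`, `f_ocean_sd`,
#'   `f_cont_sd`, flux quantiles (`f_ocean_quantiles`, `f_cont_quantiles`),
#'   `n_draws`, and optionally `mc_draws`.
#' @export
propagate_uncertainty <- function(params, n_draws = 1e5, seed = 1,
                                  keep_draws = FALSE) {
  if (n_draws < 1000) stop("n_draws must be at least 1000")
  set.seed(seed)
  draw <- params
  draw$burden <- rlnorm_match(n_draws, params$burden, params$burden_sd)
  draw$total_source <- rlnorm_match(n_draws, params$total_source, params$total_source_sd)
  draw$loss_rate <- rlnorm_match(n_draws, params$loss_rate, params$loss_rate_sd)
  draw$trend <- stats::rnorm(n_draws, params$trend, params$trend_sd)
  draw$delta_trop <- stats::rnorm(n_draws, params$delta_trop, params$delta_trop_sd)
  draw$epsilon <- stats::rnorm(n_draws, params$epsilon, params$epsilon_sd)
  draw$delta_cont <- stats::rnorm(n_draws, params$delta_cont, params$delta_cont_sd)
  draw$delta_ocean <- stats::rnorm(n_draws, params$delta_ocean, params$delta_ocean_sd)

  ds <- source_signature(draw)
  denom <- draw$delta_ocean - draw$delta_cont
  num <- with(draw, burden * trend + epsilon * loss_rate +
                total_source * (delta_trop - delta_cont))
  fo <- num / denom
  fc <- draw$total_source - fo

  out <- ocean_flux(params)
  out$delta_sources_sd <- stats::sd(ds)
  out$f_ocean_sd <- stats::sd(fo)
  out$f_cont_sd <- stats::sd(fc)
  # the flux ratio has unbounded variance whenever the continental and
  # marine uncertainty ranges overlap (denominator can approach 0), so the
  # sample SD of f_ocean never stabilises; quantiles do, and are reported
  # alongside.
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  out$f_ocean_quantiles <- stats::quantile(fo, qs)
  out$f_cont_quantiles <- stats::quantile(fc, qs)
  out$n_draws <- n_draws
  if (keep_draws) {
    out$mc_draws <- data.frame(delta_sources = ds, f_ocean = fo, f_cont = fc)
  }
  out
}
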