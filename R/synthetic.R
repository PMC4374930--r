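#' Generative specification for synthetic N2O isotope datasets
#'
#' Describes, per category, the correlated bivariate (optionally trivariate,
#' with site preference) Gaussian cloud of isotope values plus simple
#' metadata distributions so the mixing filters can be exercised. The
#' default moments are the compiled global summary statistics for the eight
#' categories (n, mean, 1-sigma and correlation of d15N vs d18O); the
#' Gaussian choice is deliberate — the standard ellipse is exactly the
#' 1-sigma contour of a bivariate Gaussian.
#'
#' Metadata models (not part of the compiled statistics; they exist solely
#' to give the filters something to act on): soil `concentration_ppb`
#' ~ lognormal(log 900, 0.8); freshwater/marine `saturation_pct`
#' ~ lognormal(log 150, 0.7); marine `depth_m` ~ Uniform(0, 300);
#' `is_emitted` flagged with probability 0.25 (soil) or 0.1 (freshwater,
#' marine); flux weights ~ lognormal(0, 1).
#'
#' @param categories which categories to include.
#' @param seed master seed; generation is deterministic given the spec.
#' @param sp_mean,sp_sd,sp_cor site-preference mean/SD per-mil and its
#'   correlation with d15N_bulk; `sp_sd = NULL` disables SP generation.
#' @return a list of class `n2o_synthspec`: per-category `n`, `mean`
#'   (d15N, d18O), `sd`, `r`, plus metadata and flux models.
#' @export
synthetic_spec <- function(categories = n2o_categories(), seed = 1,
                           sp_mean = 15, sp_sd = NULL, sp_cor = 0) {
  defaults <- list(
    stratosphere     = list(n = 288, mean = c(20.31, 56.39), sd = c(20.79, 18.44), r = 0.9994),
    troposphere      = list(n = 225, mean = c(6.55, 44.40),  sd = c(0.47, 0.34),   r = 0.3758),
    soil             = list(n = 884, mean = c(-14.85, 31.23), sd = c(12.01, 9.89), r = 0.6083),
    freshwater       = list(n = 738, mean = c(-4.65, 41.77), sd = c(9.84, 8.79),   r = 0.6656),
    marine           = list(n = 495, mean = c(6.63, 47.35),  sd = c(3.50, 9.54),   r = 0.4866),
    groundwater      = list(n = 530, mean = c(-13.97, 45.34), sd = c(15.46, 17.74), r = 0.4552),
    Antarctic        = list(n = 35,  mean = c(-40.84, 29.03), sd = c(30.75, 31.82), r = 0.2256),
    urban_wastewater = list(n = 92,  mean = c(-11.56, 31.51), sd = c(12.70, 14.14), r = 0.2922)
  )
  unknown <- setdiff(categories, names(defaults))
  if (length(unknown)) stop("unknown category: ", paste(unknown, collapse = ", "))
  structure(
    list(categories = defaults[categories], seed = as.integer(seed),
         sp_mean = sp_mean, sp_sd = sp_sd, sp_cor = sp_cor,
         meta = list(
           soil_conc_meanlog = log(900), soil_conc_sdlog = 0.8,
           sat_meanlog = log(150), sat_sdlog = 0.7,
           marine_depth_max = 300,
           p_emitted = c(soil = 0.25, freshwater = 0.1, marine = 0.1),
           flux_meanlog = 0, flux_sdlog = 1)),
    class = "n2o_synthspec")
}

#' Generate synthetic records for one category
#'
#' Draws `n` records from the category's correlated Gaussian isotope
#' distribution (via [MASS::mvrnorm()]) with the metadata described in
#' [synthetic_spec()]. Deterministic: the category's stream is derived from
#' the spec's master seed and the category name, so regenerating any one
#' category reproduces it byte-for-byte.
#'
#' @param spec an [synthetic_spec()].
#' @param category one of the spec's categories.
#' @param n optional override of the category sample size.
#' @return an [n2o_dataset()].
#' @export
generate_category <- function(spec, category, n = NULL) {
  stopifnot(inherits(spec, "n2o_synthspec"))
  cs <- spec$categories[[category]]
  if (is.null(cs)) stop("category not in spec: ", category)
  if (is.null(n)) n <- cs$n
  if (n == 0) {
    return(n2o_dataset(data.frame(category = character(0),
                                  d15N_bulk = numeric(0), d18O = numeric(0))))
  }
  idx <- match(category, names(spec$categories))
  set.seed(spec$seed * 1000L + idx)

  with_sp <- !is.null(spec$sp_sd)
  if (with_sp) {
    sds <- c(cs$sd, spec$sp_sd)
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- cs$r
    R[1, 3] <- R[3, 1] <- spec$sp_cor
    Sigma <- diag(sds) %*% R %*% diag(sds)
    mu <- c(cs$mean, spec$sp_mean)
  } else {
    cv <- cs$r * cs$sd[1] * cs$sd[2]
    Sigma <- matrix(c(cs$sd[1]^2, cv, cv, cs$sd[2]^2), 2, 2)
    mu <- cs$mean
  }
  if (any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    stop("correlation structure is not positive semi-definite")
  }
  draws <- MASS::mvrnorm(n, mu, Sigma)
  draws <- matrix(draws, ncol = length(mu))   # n = 1 safety

  df <- data.frame(category = category,
                   d15N_bulk = draws[, 1], d18O = draws[, 2])
  if (with_sp) {
    df$site_preference <- draws[, 3]
    df$d15N_alpha <- df$d15N_bulk + df$site_preference / 2
    df$d15N_beta <- df$d15N_bulk - df$site_preference / 2
  }

  m <- spec$meta
  df$concentration_ppb <- NA_real_
  df$saturation_pct <- NA_real_
  df$depth_m <- NA_real_
  df$is_emitted <- NA
  df$flux <- NA_real_
  if (category == "soil") {
    df$concentration_ppb <- stats::rlnorm(n, m$soil_conc_meanlog, m$soil_conc_sdlog)
  }
  if (category %in% c("freshwater", "marine")) {
    df$saturation_pct <- stats::rlnorm(n, m$sat_meanlog, m$sat_sdlog)
  }
  if (category == "marine") {
    df$depth_m <- stats::runif(n, 0, m$marine_depth_max)
  }
  if (category %in% names(m$p_emitted)) {
    df$is_emitted <- stats::runif(n) < m$p_emitted[[category]]
    df$flux <- stats::rlnorm(n, m$flux_meanlog, m$flux_sdlog)
  }
  df$site <- paste0("synthetic-", category)
  df$reference <- "synthetic"
  n2o_dataset(df)
}

#' Generate a full synthetic dataset across categories
#'
#' @inheritParams generate_category
#' @return an [n2o_dataset()] with all the spec's categories stacked.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "n2o_synthspec"))
  parts <- lapply(names(spec$categories), function(cc) {
    as.data.frame(generate_category(spec, cc))
  })
  n2o_dataset(do.call(rbind, parts))
}

#' Draw a mixture observation from known proportions
#'
#' The forward model of the mixing analysis: tracer `j` is drawn
#' `Normal(sum_k p_k mu_kj, sqrt(sum_k p_k^2 sigma_kj^2 + noise_sd_j^2))`.
#' Used to build parameter-recovery problems with known ground truth.
#'
#' @param p source proportions on the simplex.
#' @param source_means,source_sds K x J matrices as in [mixing_problem()].
#' @param noise_sd per-tracer additional noise (scalar or length J).
#' @param seed integer seed.
#' @return length-J vector of mixture tracer values.
#' @export
generate_mixture_observation <- function(p, source_means, source_sds,
                                         noise_sd = 0, seed = 1) {
  source_means <- as.matrix(source_means)
  source_sds <- as.matrix(source_sds)
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) stop("p must lie on the simplex")
  if (length(p) != nrow(source_means)) stop("dimension mismatch: p vs sources")
  if (!all(dim(source_sds) == dim(source_means))) stop("dimension mismatch: sds")
  J <- ncol(source_means)
  noise_sd <- rep_len(noise_sd, J)
  set.seed(seed)
  mu <- colSums(p * source_means)
  sd <- sqrt(colSums(p^2 * source_sds^2) + noise_sd^2)
  stats::rnorm(J, mu, sd)
}

#' Fixture dataset straddling every filter threshold
#'
#' Builds a small deterministic dataset whose records sit on both sides of
#' the 650 ppb soil-concentration threshold, the 200% saturation threshold,
#' and the 100 m marine depth cut, plus emitted-flag, missing-metadata and
#' ineligible-category cases. The expected per-category kept counts are
#' attached as the `"expected_kept"` attribute.
#'
#' @param seed seed for the (small) isotope-value noise.
#' @return an [n2o_dataset()] with an `expected_kept` attribute.
#' @export
generate_filter_fixture <- function(seed = 1) {
  set.seed(seed)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)

  # soil: concentrations 600..700 in 10-ppb steps -> 5 kept (strict > 650)
  add(category = "soil", concentration_ppb = seq(600, 700, by = 10),
      is_emitted = FALSE)
  # soil flagged emitted despite ambient concentration -> kept
  add(category = "soil", concentration_ppb = 330, is_emitted = TRUE)
  # soil with no concentration and no flag -> insufficient metadata
  add(category = "soil", concentration_ppb = NA_real_, is_emitted = NA)

  # freshwater saturations straddling 200% -> 2 kept (201, 250)
  add(category = "freshwater", saturation_pct = c(150, 199, 200, 201, 250),
      is_emitted = FALSE)

  # marine: saturated but only the top 100 m (or unknown depth) is kept
  add(category = "marine", saturation_pct = 250,
      depth_m = c(50, 100, 101, 150), is_emitted = FALSE)
  add(category = "marine", saturation_pct = 250, depth_m = NA_real_,
      is_emitted = FALSE)
  add(category = "marine", saturation_pct = 150, depth_m = 50,
      is_emitted = FALSE)

  # ineligible categories never survive, whatever their metadata
  add(category = "troposphere", is_emitted = TRUE)
  add(category = "groundwater", saturation_pct = 300, is_emitted = TRUE)

  df <- do.call(rbind, lapply(rows, function(r) {
    base <- data.frame(category = r$category,
                       concentration_ppb = NA_real_, saturation_pct = NA_real_,
                       depth_m = NA_real_, is_emitted = NA)
    for (col in names(r)) base[[col]] <- r[[col]]
    base
  }))
  df$d15N_bulk <- stats::rnorm(nrow(df), -10, 5)
  df$d18O <- stats::rnorm(nrow(df), 35, 5)
  out <- n2o_dataset(df)
  attr(out, "expected_kept") <- c(soil = 6L, freshwater = 2L, marine = 3L)
  out
}
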