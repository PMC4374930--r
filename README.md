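# n2osource

Apportionment of global nitrous oxide (N₂O) sources from stable isotope
measurements.

Atmospheric N₂O is rising, and mitigating it requires knowing how much of
the flux comes from soils, freshwaters, and the ocean. Because microbial
N₂O production fractionates isotopes, compiled in-situ measurements of
δ¹⁵N-N₂O (vs air-N₂), δ¹⁸O-N₂O (vs VSMOW), and the ¹⁵N site preference
SP = δ¹⁵Nᵅ − δ¹⁵Nᵝ carry a source fingerprint. This package implements the
complete "bottom-up" analysis chain for users working with such
compilations: geochemists and biogeochemists apportioning trace-gas
budgets, and anyone needing standard-ellipse summaries or a transparent,
dependency-light Bayesian isotope mixing model in base R.

## What it computes

**Standard ellipses.** A category of bivariate isotope data is summarised
by its 1σ ellipse: centred on the mean, semi-axes a ≥ b from the
eigenvalues of the sample covariance matrix, orientation
θ = ½·atan2(2 cov, σₓ² − σᵧ²), and sample-size-corrected area
SEAc = π·a·b·(n−1)/(n−2). The ellipse contains ≈39.4% of bivariate-normal
data.

**Mixing filters.** Records dominated by mixing with tropospheric N₂O are
removed: keep a record iff it is reported emitted N₂O, or soil gas with
concentration > 650 ppb v/v, or freshwater / upper-ocean (depth ≤ 100 m)
water > 200% saturation. Soil + freshwater pool into the *continental*
source.

**Two-box isotope mass balance.** With the tropospheric burden, the
observed trend ∂δ_Trop/∂t, the stratospheric loss L and enrichment factor
ε, and the total source ΣSources,

    δ_Sources = [Burden·∂δ_Trop/∂t + ε·L + ΣSources·δ_Trop] / ΣSources
    F_Ocean   = [Burden·∂δ_Trop/∂t + ε·L + ΣSources·(δ_Trop − δ_Cont)] / (δ_Ocean − δ_Cont)

with F_Cont = ΣSources − F_Ocean, plus Monte-Carlo uncertainty
propagation and a loss-rate sensitivity scenario.

**Bayesian mixing model.** Source proportions p on the simplex with a
Dirichlet(α) prior and likelihood
δ_mix,j ~ N(Σₖ pₖμₖⱼ, √(Σₖ pₖ²σₖⱼ² + σ_mix,j²)), sampled by adaptive
random-walk Metropolis in softmax coordinates, with Gelman-Rubin and
Geweke diagnostics.

**Synthetic data.** A seeded generator reproduces the per-category
correlated Gaussian structure (defaults are the compiled global category
statistics) plus filter metadata and flux weights, so the whole pipeline
runs and is tested without any external download.

## Worked example

```r
library(n2osource)

# global mean source signature and ocean/continental partition (d15N)
fit <- propagate_uncertainty(box_model_params("15N"), n_draws = 1e5, seed = 1)
print(fit)
#> Two-box N2O isotope mass balance (15N)
#>   mean source signature: -8.39 (+- 5.18) per-mil
#>   F_ocean: 4.63 Tg N/yr (26%, MC 95% interval [-89.3, 91.9])
#>   F_cont:  13.27 Tg N/yr (74%, MC 95% interval [-73.6, 106.9])
#>   net isotope flux (-epsilon*L): 213.1 per-mil Tg N/yr
#>   uncertainties: Monte-Carlo, 1e+05 draws
```

The modern mean source (−8.4 ‰, δ¹⁵N) is far lighter than the troposphere
(6.55 ‰) because the isotopically light surface sources are balanced by
the heavy return flux from the stratosphere. The point partition
attributes ~26% of the total source to the ocean; the enormous MC
interval on the flux is real — it is a ratio whose denominator
(δ_Ocean − δ_Cont) can approach zero under the continental uncertainty —
and is why the signature, not the flux, is the robust output of the
mass balance.

```r
# filtered marine ellipse from its summary statistics
print(ellipse_from_stats(5.14, 44.76, 1.93, 3.62, r = 0.0435, n = 62))
#> Standard ellipse (n = 62)
#>   centre     (5.14, 44.76)
#>   sigma      (1.93, 3.62), r = 0.0435
#>   semi-axes  a = 3.621, b = 1.927, theta = 1.538 rad, slope = 30.89
#>   corrected ellipse area = 22.29

# synthetic end-to-end: simulate, filter, then mix back to proportions
set.seed(1)
d   <- generate_dataset(synthetic_spec(seed = 1))
f   <- filter_source_subset(d)
src <- mixing_sources_from_data(f)
fit <- fit_mixing_model(mixing_problem(src$means, src$sds, c(-8.39, 31.71)),
                        mcmc_settings(30000, 10000, 10, 3, seed = 1))
print(fit)
#> Bayesian isotope mixing model (2 tracers, 3 sources)
#>   6000 retained draws (3 chains, thinning 10)
#>             mean    sd  q2.5   q50 q97.5 rhat
#> soil       0.456 0.207 0.051 0.464 0.854    1
#> freshwater 0.334 0.230 0.015 0.300 0.835    1
#> marine     0.210 0.147 0.009 0.186 0.541    1
```

Feeding the box-model source signature back into the mixing model
attributes most of the modern source to the continental categories, with
wide credible intervals — the soil and freshwater clouds overlap heavily
in δ¹⁵N–δ¹⁸O space, so only their sum is well constrained by two tracers.

`run_full_analysis(list(out_dir = "out", seed = 1))` chains all stages
and writes the category tables, box-model JSON, mixing posterior and a
run log; `inst/scripts/n2o-pipeline.R` exposes the same stages as shell
subcommands (`simulate`, `filter`, `ellipses`, `boxmodel`, `mix`,
`run-all`).

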