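---
title: "Apportioning global N2O sources from stable isotopes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apportioning global N2O sources from stable isotopes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2osource)
```

## The problem

Nitrous oxide is the third most important long-lived greenhouse gas and the
dominant remaining threat to stratospheric ozone, yet the relative strengths
of its surface sources — soils, freshwaters, and the ocean — are uncertain.
Because microbial production pathways fractionate nitrogen and oxygen
isotopes differently, the stable isotope composition of N2O
(δ¹⁵N vs air-N₂, δ¹⁸O vs VSMOW, and the ¹⁵N site preference between the
central and terminal nitrogen of the linear NNO molecule) carries a source
fingerprint. `n2osource` implements the full chain of a "bottom-up"
isotope-based apportionment:

1. a data model and CSV I/O for compiled in-situ isotope records
   (`read_n2o_dataset()`, `write_n2o_dataset()`);
2. rule-based filtering of measurements dominated by mixing with
   tropospheric N2O (`filter_source_subset()`);
3. bivariate standard-ellipse summaries per source category
   (`standard_ellipse()`);
4. a two-box tropospheric isotope mass balance with Monte-Carlo uncertainty
   propagation (`source_signature()`, `ocean_flux()`,
   `propagate_uncertainty()`);
5. a Dirichlet-prior Bayesian isotope mixing model with MCMC
   (`fit_mixing_model()`);
6. a seeded synthetic-data generator that reproduces the statistical
   structure the analysis assumes (`synthetic_spec()`,
   `generate_dataset()`), so that every stage is testable offline.

## Data model and filtering

Records carry the two delta values, optional isotopomer deltas and site
preference (validated against SP = δ¹⁵Nα − δ¹⁵Nβ and
δ¹⁵N_bulk = (δ¹⁵Nα + δ¹⁵Nβ)/2 to 0.05 ‰), one of eight category labels,
and the metadata the filters need: N2O concentration (ppb v/v), dissolved
saturation (% of atmospheric equilibrium), depth (m), an emitted-N2O flag,
and an optional flux weight. Missing optional fields are `NA`, never zero.
Parsing resolves common column-name variants through an alias table,
rejects malformed rows with enumerated reasons (never silently), and in
lenient mode remaps category synonyms such as "ocean" → "marine".

Low-concentration soil gas and near-equilibrium surface waters mostly
record tropospheric N2O rather than the local source, so the source
subset retains a record only if it is an explicit report of emitted N2O,
or soil gas above 650 ppb v/v, or freshwater/upper-ocean water
(depth ≤ 100 m, or depth not reported for surface samples) above 200%
saturation. All thresholds are strict inequalities. A record that is
eligible for a criterion but lacks the field the criterion needs is
excluded and counted under "insufficient metadata" — guessing is worse
than dropping. The soil and freshwater subsets are pooled into the
operational *continental* source (`pool_continental()`); the filtered
marine subset is the *ocean* source.

Two wording ambiguities were settled as follows. "Near-surface marine"
is implemented as depth ≤ 100 m (the top 100 m of the ocean), because
that is the reading consistent with the filtered marine sample size the
analysis relies on. The soil criterion "650 ppb v/v (or 200% ambient)"
is implemented as the single ppb threshold, reading the parenthetical as
a restatement rather than a second rule. The emitted-N2O criterion is an
explicit boolean in the data because flux-chamber provenance cannot be
inferred from the delta values themselves.

## The standard ellipse

For a bivariate sample the standard ellipse is the 1σ contour: centred on
the mean, with semi-axes a ≥ b equal to the square roots of the
eigenvalues of the sample covariance matrix (n − 1 denominator; the
choice is validated by reproducing the published category tables). The
orientation is θ = ½·atan2(2·cov, σₓ² − σᵧ²), mapped into [0, π). For a
bivariate Gaussian the ellipse contains exactly 1 − e^(−1/2) ≈ 39.35% of
the probability mass — the "∼40% of the data" property, which
`containment_fraction()` checks by counting squared Mahalanobis distances
≤ 1. The sample-size-corrected ellipse area is

SEAc = π · a · b · (n − 1)/(n − 2),

which removes the small-sample bias of the raw area. Numerical choices:

* a perfectly circular cloud (σₓ = σᵧ, r = 0) has no defined orientation;
  θ is reported as 0 deterministically;
* the slope of the major axis equals tan θ but is computed as
  (λ₁ − σₓ²)/cov when cov ≠ 0, which is stable for near-vertical ellipses
  (tan θ blows up as θ → π/2);
* exactly collinear input is flagged degenerate with b = 0 and SEAc = 0
  rather than failing; containment and tangency are refused for
  degenerate ellipses;
* fewer than 3 points is an error.

`tangency_points()` returns where the vertical and horizontal tangent
lines touch the ellipse — (x̄ ± σₓ, ȳ ± rσᵧ) and (x̄ ± rσₓ, ȳ ± σᵧ) —
which are also the intersections with the two regression lines.
`ols_line()` (a thin wrapper over `lm`) serves the stratospheric
destruction line in δ¹⁵N–δ¹⁸O space, and `mann_whitney()` compares
category medians: the U statistic by mid-rank summation, with the exact
null distribution when n₁·n₂ ≤ 400 and no ties are present, and a
tie-corrected normal approximation (no continuity correction) otherwise.

## The two-box isotope mass balance

The troposphere is one well-mixed box; stratospheric photodestruction
removes N2O at rate L with apparent enrichment factor ε, and all surface
sources add ΣSources per year with flux-weighted mean signature
δ_Sources. The observed slow decline of the tropospheric delta then
constrains the mean source:

Burden · ∂δ_Trop/∂t = ΣSources · (δ_Sources − δ_Trop) − ε·L

δ_Sources = [Burden · ∂δ_Trop/∂t + ε·L + ΣSources · δ_Trop] / ΣSources.

The −ε·L term is the net isotope flux returned from the stratosphere
(‰·Tg N yr⁻¹). Splitting ΣSources into a continental and an ocean
endmember with signatures δ_Cont, δ_Ocean gives the partition

F_Ocean = [Burden · ∂δ_Trop/∂t + ε·L + ΣSources · (δ_Trop − δ_Cont)] /
          (δ_Ocean − δ_Cont),   F_Cont = ΣSources − F_Ocean,

singular exactly when the endmembers are isotopically indistinguishable.
`sensitivity_scenario(params, dL)` moves dL Tg N yr⁻¹ from L to
ΣSources, the perturbation under which the oxygen-isotope balance turns
its negative ocean flux positive.

Defaults (all overridable, units in the help page): burden
1553 ± 21.742 Tg N; trends −0.035 ± 0.002 (δ¹⁵N) and −0.022 ± 0.004
(δ¹⁸O) ‰ yr⁻¹; ΣSources 17.9 Tg N yr⁻¹ ± 25%; L 14.3 Tg N yr⁻¹ ± 25%;
ε −14.9 ± 0.5 and −13.5 ± 0.5 ‰; tropospheric deltas 6.55 ± 0.47 and
44.40 ± 0.34 ‰; continental −13.11 ± 11.51 and 34.32 ± 10.96 ‰; marine
5.14 ± 1.93 and 44.76 ± 3.62 ‰. The tropospheric delta uncertainties are
the category-table standard deviations, the natural choice given that
the propagation inputs are otherwise category statistics.

**Uncertainty propagation** is Monte-Carlo rather than first-order
Taylor, because the flux partition is a ratio whose nonlinearity
first-order propagation understates. Design choices that matter:

* one draw uses a single ΣSources value everywhere it appears — it is
  physically one quantity;
* delta values, trends and ε are Gaussian; the strictly positive budget
  quantities (burden, ΣSources, L) are lognormal with matching mean and
  SD. A Gaussian truncated at zero was rejected deliberately: truncation
  leaves finite density near ΣSources = 0, so δ_Sources ∝ 1/ΣSources has
  *infinite variance* and its sample SD grows without bound as draws
  accumulate. The lognormal keeps every ratio moment finite while
  matching the stated mean and relative uncertainty;
* the F_Ocean ratio is more delicate still: its denominator
  δ_Ocean − δ_Cont crosses zero with non-negligible probability under
  the continental uncertainty (±11.5 ‰), so the flux's variance is
  unbounded *regardless* of how the positive quantities are drawn. The
  sample SD is reported (it is the conventional summary) but the
  quantiles reported alongside (`f_ocean_quantiles`) are the stable
  description of the flux uncertainty, and convergence tests are run on
  the signature SD, which is well-defined;
* point estimates are always the deterministic evaluations, never MC
  means; the partition closes exactly (F_Ocean + F_Cont = ΣSources).

## The Bayesian mixing model

The flux-weighted modern source is modelled as a convex combination of
the soil, freshwater and marine endmembers on J = 2 or 3 tracers
(δ¹⁵N_bulk, δ¹⁸O, optionally SP):

δ_mix,j ~ Normal( Σₖ pₖ μₖⱼ , √(Σₖ pₖ² σₖⱼ² + σ_mix,j²) ),
p ~ Dirichlet(α),  α = (1, …, 1) by default.

This is the fully specified ("weighted-variance") mixing likelihood;
hierarchical process/residual error terms are a deliberate
simplification away, and source statistics are the filtered raw-data
means and SDs rather than hierarchically fitted. Sampling is adaptive
random-walk Metropolis on softmax-transformed simplex coordinates
(z ∈ ℝ^(K−1), p = softmax(z, 0)); the change-of-variables Jacobian makes
the prior term Σₖ αₖ log pₖ, so a prior-only run reproduces
Dirichlet(α) exactly in distribution — the test suite uses this as a
sampler-correctness oracle against the closed-form Dirichlet moments and
Beta marginal quantiles. The proposal scale adapts toward ≈30%
acceptance during burn-in only and is frozen afterwards, so retained
draws come from a fixed-kernel chain. One master seed spawns per-chain
streams; fits are bit-reproducible.

Default settings are the ones found adequate by convergence diagnostics
for this problem class — chain length 300,000, burn-in 200,000, thinning
50 (2 tracers) or 100 (3 tracers), 3 chains — while tests use
scaled-down runs (typically 8,000–30,000 iterations, 2 chains), which
this low-dimensional posterior mixes well within. Convergence is
reported per proportion: Gelman-Rubin R-hat across chains (floored at 1,
so identical chains report exactly 1.0; a value above 1.1 raises a
warning, never a silent result) and the Geweke early/late z score with
AR-fit spectral standard errors. Because the likelihood is exchangeable
in the source labels, permuting the labels permutes the posterior; the
usual mixture-model label-switching pathology does not arise since the
proportions, not component identities, are the parameters.

A note on reproducing the published posterior summaries for the global
problem: the mixture values (the modern average source) used there come
from an external firn-air reconstruction that the compilation does not
tabulate, and the published row labelling is internally inconsistent
(the same numbers appear with soil and marine interchanged in different
places). The package therefore never hard-codes either ordering;
posterior rows are labelled by the caller's source names.

## The synthetic generator

`synthetic_spec()` describes each category as a correlated bivariate
(optionally trivariate, with SP) Gaussian with the compiled global
category moments as defaults — Gaussian because the standard ellipse is
exactly the 1σ contour of a bivariate Gaussian, making generator truth
directly comparable to ellipse estimates. Metadata distributions exist
solely to exercise the filters and are deliberately simple, chosen once:
soil concentration lognormal(log 900, 0.8) ppb; aquatic saturation
lognormal(log 150, 0.7) %; marine depth uniform on (0, 300) m; emitted
flags with probability 0.25 (soil) and 0.1 (freshwater, marine); flux
weights lognormal(0, 1). Because the metadata are independent of the
isotope draw, filtering acts as random subsampling in isotope space and
filtered moments remain unbiased estimates of the generating moments —
which the pipeline tests exploit. What the generator does *not* emulate:
skewed and multi-modal real category distributions, within-site
autocorrelation, reporting heterogeneity between studies, and any
mechanistic dependence of isotope values on concentration or depth (in
real soil profiles the two are coupled through diffusion and mixing).
Passing recovery tests therefore demonstrates the correctness of the
estimators under the model's own assumptions, not robustness to real
survey structure.

## Reference-frame and isotopomer arithmetic

δ¹⁸O values reported against atmospheric O₂ convert to the VSMOW frame
with the exact identity δ_VSMOW = δ + c + δ·c/1000, where c is the δ¹⁸O
of atmospheric O₂ vs VSMOW; the default c = 23.88 ‰ is the modern value
and is configurable since compilations differ in the constant they used.
The conversion is strictly monotone and exactly invertible with
c′ = −c/(1 + c/1000).

## Problem sizes and determinism

The test suite runs the generator at its default category sizes (≈3,800
records), Monte-Carlo propagation at 10³–10⁵ draws, containment checks
at 2·10⁵ points, and 20-replicate mixing recovery at 30,000-iteration
chains; the full pipeline test uses 8,000–10,000-iteration chains. All
stochastic stages are seeded; reruns with the same configuration are
byte-identical, and the pipeline writes numeric artifacts at 6
significant digits for stable diffs.

## Known limitations

* Saturation is consumed as a reported field; no solubility computation
  from temperature/salinity is attempted.
* The mass balance is used only in its steady-state rearrangements; the
  tropospheric trend is not integrated forward in time.
* The mixing model omits covariates, random effects and
  concentration-dependence of source contributions.
* Flux-weighted source averaging is provided (`flux_weighted_average()`)
  but global flux-weighted syntheses remain limited by how few studies
  report flux weights at all.
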