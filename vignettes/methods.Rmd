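---
title: "Models and methods: EBSMR smoothing, first-difference panels, and spatial BYM fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phnsmr` implements a longitudinal ecological analysis linking changes in the
municipal public-health-nurse (PHN) workforce to changes in mortality. The
design is a two-period municipality panel (census years 2010 and 2015, death
counts pooled over the five fiscal years around each census), with outcomes
standardized for age and smoothed for small-area instability, analysed by a
first-difference mixed model and, as a sensitivity analysis, by a fully
Bayesian spatial Poisson model. This vignette is the package's own account of
those methods: the models, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the numerical
decisions that a maintainer would otherwise have to reverse-engineer.

## 1. Indirect standardization and the Poisson-Gamma EBSMR

For one municipality, sex, cause and period, observed deaths `o` are pooled
over a five-year window. Expected deaths come from indirect standardization:

    e = years * sum_a pop_a * rate_a

where `rate_a` are base-year national age-specific mortality rates per
person-year in five-year age groups and `years = 5` is the pooling window.
Both periods are standardized against the *same* base-year rates: under
indirect standardization an SMR is only comparable to the standard
population's value, so re-basing the second period would break the
longitudinal comparison. The raw SMR is `100 * o / e` (the base-year national
value is 100).

Raw SMRs of small municipalities are dominated by Poisson noise. The
empirical Bayes estimate assumes

    o ~ Poisson(e * theta),   theta ~ Gamma(alpha, nu)

so the posterior is `Gamma(o + alpha, e + nu)` and the EBSMR is the posterior
mean `100 * (o + alpha) / (e + nu)`, equivalently a shrinkage
`w * SMR + (1 - w) * 100 * m` with weight `w = e / (e + nu)` and prior mean
`m = alpha / nu`. Hyperparameters are estimated per prefecture group (the
prior reflects "the distribution of SMRs within the prefecture") by
Marshall's precision-weighted moment estimator:

    m = sum(o) / sum(e)
    v = sum(e * (o/e - m)^2) / sum(e) - m / mean(e)

with `nu = m / v`, `alpha = m^2 / v` when `v > 0`. The subtraction of
`m / mean(e)` removes the expected Poisson contribution to the weighted
dispersion; when `v <= 0` the between-area signal is indistinguishable from
Poisson noise and the prior is treated as degenerate, shrinking completely to
the group mean. This moment estimator is the standard recommendation in the
EB disease-mapping literature; the exact weighting used by older desktop EB
tools is not documented publicly, so Marshall's version is the package's
explicit choice.

Two guardrails are configurable:

* `min_group` (default 5 municipalities): moment estimates in tiny groups are
  unstable, so smaller prefecture groups fall back to the national pool for
  that sex x cause x period, and the fallback is recorded per row.
* Priors are fitted separately per sex x cause x period within the grouping.
  Whether the original analysis pooled sexes or causes when fitting the
  prefecture prior is not documented; per-series fitting is assumed because
  the outcome series are published separately by sex.

Expected deaths for a pooled window use the census-year population times 5;
inter-censal populations are not modelled.

## 2. First-difference panel model

With two periods, differencing removes any municipality-constant confounder;
the first-difference estimator is numerically identical to the within
(fixed-effects) estimator, and `first_difference_equals_fixed_effects()`
verifies that identity on any two-period design. The outcome is the change in
EBSMR; covariates are the difference of natural logs for PHN density and
population (both are heavy-tailed and the PHN-population relation is
log-linear) and plain differences for the other per-100k resource counts.
Per-100k denominators use the first-period population in both periods, so
density changes reflect workforce change rather than denominator drift.

The adjusted model is a *no-intercept* linear mixed model fitted by full
maximum likelihood (not REML), with a prefecture random intercept:

    dy_i = x_i' beta + u_pref(i) + e_i,   u ~ N(0, s2_u),  e ~ N(0, s2_e)

No intercept is included because a common secular trend would be absorbed by
an intercept, and the study design instead attributes the common change to
the covariates and the prefecture effects. The package fits this with
`lme4::lmer(REML = FALSE)` behind `fit_lmm_ml()`; ML (not REML) is required
for the AIC comparison against the model without the random effect, and the
AIC counts the fixed effects plus both variance components. Coefficient
p-values use Wald statistics against a normal reference by default (the
degrees-of-freedom convention of the original desktop software is unknowable;
a residual-df t reference is available via `wald_df = "residual"`).

Zero PHN densities would break the log transform. The package treats them as
an error by default, with an optional continuity offset (the smallest
positive observed value, logged) because the real registry data apparently
contained none and silently imputing would hide a data problem.

Sensitivity layers mirror the study design: the full-time/part-time variant
replaces the single PHN covariate with two; stratified analyses split at
baseline population 10,000 and baseline EBSMR 100 (strata where the mixed
model cannot be fitted fall back to the fixed-effects-only fit, recorded);
multiplicity over the four cause series is handled by Benjamini-Hochberg
q-values (`stats::p.adjust`), reported at the 0.10 level. Cohen's d with the
pooled SD quantifies size-class contrasts; VIFs (`1 / (1 - R^2)`) check
multicollinearity of the differenced covariates.

## 3. The spatial BYM model

The sensitivity analysis refits the mortality-workforce relation as a
hierarchical Poisson regression on the stacked municipality x period data:

    o_k ~ Poisson(mu_k)
    log(mu_k) = log(e_k) + x_k' beta + phi_m(k) + eps_k

with offset `log(e)`, covariates at each time point (log PHN density, log
population, per-100k resource counts, and a 0/1 time dummy), an intrinsic CAR
(ICAR) spatial field `phi` per municipality, and iid heterogeneity `eps` per
observation. `phi` is shared across the two periods of a municipality — the
model indexes the spatial field by municipality while time enters through
the dummy — and `eps` is drawn per observation. The ICAR improper density is

    p(phi | tau) propto exp(-(tau/2) * sum_{i~j} (phi_i - phi_j)^2)

defined up to a constant per connected component; identification uses a soft
sum-to-zero constraint (the component mean gets a zero-centred normal prior
with SD `0.001 * component size`), with the density rank `n - c` entering
the scale updates. The second model variant splits the PHN covariate into
the baseline (2010) log density, applied to both periods, and the change
(difference of logs), active only in the second period through the time
dummy. A difference of logs is used for the change because that is the
transform the first-difference model uses; the alternative reading (log of a
possibly negative difference) is not well defined.

**Priors.** The original analysis's priors are in supplementary material that
is not publicly reproduced, so the package documents its own weakly
informative defaults: `beta_j ~ N(0, 5)` per natural-scale coefficient and
half-normal(1) on both scale parameters. Estimates are *reported* with the
adjustment covariates scaled by 1/1000 (draws multiplied by 1000), matching
the study's reporting convention. The prior is deliberately placed on the
natural scale: placing N(0, 5) literally on the 1/1000-scale coefficients
would shrink effects of the reported magnitude (tens) several-fold, which is
not a weakly informative choice. The sampler is exactly equivariant under
jointly rescaling a covariate and its prior/proposal scales, and a test
pins that property.

**Sampler.** No installed library provides ICAR-structured MCMC, so the
sampler is written in C++ (Rcpp): adaptive Metropolis-within-Gibbs with
single-site updates for `phi` and `eps`, componentwise and joint adaptive
multivariate updates for `beta`, and log-scale updates for the two scales.
Two extra move families are essential in this model:

* *Ridge moves.* Municipality-level covariates are confounded with the free
  spatial field — `beta_j` and `phi` can trade off along directions the
  likelihood barely constrains. Each iteration proposes `beta_j` jumps with a
  compensating translation of `phi` by the municipality means of `x_j` (and
  the joint multivariate version of the same), so the chain travels along
  the weakly identified ridge at prior-limited step sizes instead of
  likelihood-limited ones.
* *Funnel moves.* Joint rescalings of `(sigma_phi, phi)` and
  `(sigma_eps, eps)` handle the scale-field funnels; the ICAR quadratic form
  is invariant under the first, which makes it cheap.

Proposal scales adapt towards 0.44 acceptance (0.24 for the joint move) in
50-iteration batches with diminishing adaptation, frozen after warmup.
Defaults are 4 chains of 12,000 iterations (4,000 warmup). Convergence is
summarised by split-chain R-hat and an effective sample size using Geyer's
initial positive sequence; a fit is flagged converged when all reported
parameters have R-hat < 1.05 and ESS >= 400. Correctness is established by
three reductions tested in the suite: with both random components off the
posterior matches the ML Poisson regression; prior-only sampling reproduces
the documented priors; and on data generated from the model the 95% quantile
credible interval for the PHN coefficient covers the truth at the nominal
rate across replicate fits.

Poisson log-density terms clamp the linear predictor at 700 before
exponentiation (overflow proposals are rejected); quantile credible
intervals use the type-7 empirical quantile convention and require at least
100 retained draws.

## 4. The synthetic-data generator

`generate_panel()` produces the full data structure with a recorded ground
truth, so every stage is testable without registry data. It emulates:

* log-normal municipal populations (`mu = 10.2025`, `sigma = 0.9961`, chosen
  analytically so the natural-scale mean and SD are near 44,300 and 57,700);
* PHN density decreasing with population size,
  `ln(PHN per 100k) = 8.7 - 0.5 ln(pop) + N(0, 0.3)`, calibrated to around
  43 per 100k overall and around 85 below 10,000 inhabitants;
* other healthcare resources with log-linear population relations calibrated
  to the same descriptive table (physicians increase with size, clinics,
  hospitals and welfare facilities decrease);
* gamma-distributed municipal relative risks (`Gamma(70, 70)`, log-SD about
  0.12, between the dispersion of the all-cause and cause-specific series)
  clustered by prefecture (log-normal prefecture shift, SD 0.05);
* an ICAR spatial field sampled exactly by eigen-decomposition of the graph
  Laplacian restricted to the sum-to-zero subspace (SD 0.05), over a
  rectangular-grid adjacency (always connected; a random-geometric
  alternative, densified by a spanning tree when disconnected, sits behind a
  config switch);
* a secular mortality decline of -0.08 on the log scale between periods
  (about -8 EBSMR points, the magnitude of the observed all-cause decline);
* a default PHN effect on log relative risk of -0.05 per unit ln(PHN per
  100k), applied to centred covariates so the panel stays calibrated at the
  reference level 100;
* reference mortality rates following a Gompertz age curve (log-slope 0.09
  per year) with each sex-cause level calibrated so the implied crude rates
  match the study's descriptive magnitudes under one fixed national age
  pyramid.

Deaths are then `o ~ Poisson(e * theta)` with
`theta = r * exp(pref + x'beta_centred + phi + eps + time_effect * t)`.
A fixed seed makes the output byte-identical.

What it does **not** emulate: real Japanese geography and adjacency,
municipal mergers, migration, differential age pyramids (one national
pyramid is shared, with an optional old-age tilt), inter-censal population
dynamics, and the administrative exclusions of the real sample (those are
modelled only as generic `exclude_*` flags consumed by `filter_panel()`).
Passing tests on this generator therefore demonstrate that the estimators
recover known structure of the assumed models — not that the substantive
epidemiological findings transfer to real registry data.

## 5. Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to what the
statistical check needs rather than to the full study scale: oracle and
property checks run on small randomized grids; mixed-model coverage uses 200
replicates at n = 1600 with 47 groups; BYM recovery uses 20 replicate fits
of 200 municipalities x 2 periods (the full 1,601-municipality fit runs in
the analysis scripts, where a single fit takes on the order of a minute).
The analysis workflow under `analysis/` is numbered and file-driven: stage
01 simulates and writes delimited tables, stages 02-04 each read the
previous stage's output, and stage 05 collates the report, so every number
in `results/report/` is regenerable from the generator seed recorded in the
manifest. All randomness — generator, mixed-model simulations, and MCMC —
is seed-pinned; rerunning any stage with the same seed reproduces its output
byte for byte.

## 6. Known limitations

* The EBSMR prior is fitted per prefecture group from the same data it then
  smooths; no correction for hyperparameter uncertainty is applied (standard
  for EB, but credible statements about individual EBSMRs inherit it).
* The BYM model is fitted without an intercept (the reporting convention of
  the study); the overall level must be absorbed by the covariates, so
  coefficient posteriors of level-carrying covariates (log population in
  particular) should be read as calibration parameters, not effects.
* Wald inference in the mixed model uses a normal reference; with 47
  prefectures the difference from a t reference is small but not zero.
* The sampler is random-walk based: efficient here because of the ridge and
  funnel moves, but posterior tails of weakly identified covariate
  combinations mix more slowly than gradient-based samplers would; the ESS
  threshold exists precisely to flag that.
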