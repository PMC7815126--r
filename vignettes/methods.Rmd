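---
title: "Methods: small-area space-time smoothing of child mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area space-time smoothing of child mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Household surveys with full birth histories (FBH) record, for every woman
aged 15–49, the date of each of her births and, for children who died, the
age at death. From these one can estimate the probability of dying between
birth and age 5 (₅q₀) and between exact ages 5 and 15 (₁₀q₅) — but surveys
are powered for national estimates, and at the Admin-1 × 4-year-period
level the direct estimates are noisy, frequently unusably so for the
low-mortality 5–14 age range. `mortsmooth` implements the two-stage
"smoothed direct estimates" approach: design-based direct estimation first,
then Bayesian space-time smoothing of the resulting logits treated as
Gaussian observations with known variances.

## Stage 1: direct estimation

**Person-month expansion.** Each child contributes one record per month of
age lived: months `0 … a-1` for a child alive with `a` completed months at
interview (the interview month is incomplete exposure and is dropped), and
months `0 … d` for a child dying at age `d`, the death month counting as a
full exposed month with the event indicator set. Ages are CMC differences
(completed months); day-level dates are out of scope.

**Age bands.** Under-5: `[0,1)`, `[1,12)`, and four one-year bands (widths
1, 11, 12, 12, 12, 12 months — the first band isolates neonatal mortality).
Ages 5–14: ten one-year bands over months `[60, 180)`.

**Band fits.** With age-band indicators as the only covariates the weighted
logistic likelihood is saturated, so `beta_a` is the logit of the weighted
death proportion among band-a person-months. The covariance of `beta` is
the Taylor-linearization (sandwich) estimator with clusters as primary
sampling units nested in strata, including the `n_h/(n_h−1)` factor;
strata with a single sampled cluster are centred at the grand mean
(lonely-PSU convention — the design never produces them, but real extracts
can).

**Life-table combination and delta method.** The block probability is
`q = 1 − ∏_a (1 − expit(beta_a))^{n_a}`; the variance of `logit(q)` is
`g' Σ g` with the analytic gradient `g_a = n_a p_a / q`. A band with zero
deaths or zero survivors makes the cell `status = "missing"` — no
continuity correction is applied, because the smoothing stage handles
missing cells naturally and ad-hoc corrections would distort the variance.

**Periods and truncation.** Periods are 48-month calendar intervals
anchored so the most recent survey's fieldwork end closes the last period.
Each survey reaches back at most 24 years (≤ 6 periods) for under-5 and 12
years (≤ 3 periods) for 5–14; a survey whose calendar overlap with a period
is ≤ 12 months does not inform it. The "only one year of exposure" rule is
not stated as strict or weak in the source; we implement `≤ 12` and expose
`min_exposure_months`.

## Stage 2: pooling

Surveys observing the same cell are combined as a fixed-effect
meta-analysis **on the logit scale** (the scale of the smoothing
likelihood): pooled value `Σ(x_s/V_s)/Σ(1/V_s)`, variance `1/Σ(1/V_s)`.
HIV correction factors — external inputs, multiplicative on the under-5
probability scale — are applied *after* pooling, with the logit variance
carried over unchanged; 5–14 estimates are never adjusted. Factor lookup
resolves an Admin-1 match before a country match, and a listed
country/area missing a period factor is an error rather than a silent
pass-through.

## Stage 3: the space-time model

For each age group independently,

```
logit(q̂_it) ~ N(λ_it, V̂_it)        (V̂ known, from stage 2)
λ_it = μ + α_t + γ_t + θ_i + φ_i + δ_it
```

* `μ` flat; `α_t ~ iid N(0, σα²)`; `θ_i ~ iid N(0, σθ²)`;
* `γ` ~ RW2 with structure `D₂'D₂` (penalises second differences; null
  space = constant + linear);
* `φ` ~ ICAR with structure `D − A` (graph Laplacian);
* `δ` ~ type IV interaction with structure `Q_RW2 ⊗ Q_ICAR` — neighbouring
  areas have similar deviations from the common trend;
* precisions `1/σ²` ~ Gamma(a, b), default `a = 0.5, b = 0.00149`, a
  common weakly-informative choice in this literature (the source defers
  the exact values to its references); both configurable.

**Identifiability.** `γ` is constrained to sum to zero but keeps its
linear trend (the overall trend is deliberately attributed to the
structured time component); `φ` sums to zero within every connected
component; isolated (degree-0) areas keep `φ = 0` and are carried by `θ`.
The interaction constraints span the *full* null space of `Q_RW2 ⊗ Q_ICAR`:
each area's `δ` time-series is orthogonal to both the constant and the
linear sequence, and each period's spatial field sums to zero per
component — leaving `(T−2)(n−c)` free dimensions. Plain row/column
sum-to-zero constraints would leave area-specific linear trends in `δ`,
confounded with `γ` + `φ`.

**Inference.** Given the variances the model is jointly Gaussian, so we
use a conjugate Gibbs sampler rather than an external gradient-based MCMC
engine: `μ`, `α`, `θ` have scalar Gaussian conditionals; `γ`, `φ`, `δ`
are sampled from their Gaussian full conditionals subject to the linear
constraints by conditioning-by-kriging (sample unconstrained from the
Cholesky factor, then project); precisions are conjugate Gamma updates
using the structure-matrix ranks (T−2 for RW2, n−c for ICAR, (T−2)(n−c)
for the interaction). Numerical safeguards: a `1e-8`-scaled ridge is added
only if a Cholesky factorisation fails, and the kriging solve falls back
to an eigenvalue pseudo-inverse when the constraint Gram matrix is
numerically singular (possible when the structured precision dominates and
cells are missing). Missing cells contribute no likelihood term and
receive `λ` draws from the structure — "borrowing strength"; first/last
period cells are reported with their (wide) intervals rather than dropped.
Split-half R̂ across chains is reported per cell; values above 1.05 warn
and clear the `converged` flag. Defaults: 4 chains, 1000 warmup, 1000 kept
draws per chain.

**Structure scaling.** Unscaled intrinsic priors have marginal variances
that depend strongly on T and on the graph, so σ² values are not
comparable across components. `scale_structure = TRUE` (off by default, in
both the generator and the sampler) rescales each structure matrix so the
constrained prior's average marginal variance equals its σ². The
variance-decomposition simulation check relies on this to translate a 4:1
generative variance ratio into a ~4:1 share ratio.

## Downstream summaries

* **Precision**: CV = 100 · posterior SD / posterior mean of `q` — computed
  on the probability scale (scale-invariant, so per-1000 rates give the
  same value). `CV ≥ 20%` ⇒ imprecise (threshold configurable, supporting
  the 15% sensitivity variant); a period is retained iff the share of
  precise areas is ≥ 0.75.
* **Correlation**: for each posterior draw, the Pearson correlation of the
  two age groups' `q` across the selected cells; the point estimate is the
  median of draw-wise correlations (percentile-coherent with the 2.5/97.5
  interval — the source does not state its point rule, so both the median
  and the interval come from the same draw-wise distribution).
  Correlations are computed on the probability scale. Scopes with < 3
  points are skipped with a message.
* **Variance decomposition**: each component's variance is the empirical
  variance of its posterior-mean effect vector over its own index set,
  normalised to shares summing to 100. Intrinsic precision hyperparameters
  are *not* marginal variances, so hyperparameter-based shares would not
  be comparable across components; the source does not specify its
  estimator, and this choice is flagged when comparing to published
  tables.

## The synthetic-data generator

The generator emulates exactly the structure the analysis assumes:

* a latent surface per age group drawn from the model priors (spectral
  sampling on the positive eigenspace imposes every sum-to-zero constraint
  exactly), with configurable component variances and level;
* block probabilities `expit(λ_it)` split into per-band monthly
  probabilities with band multipliers proportional on the hazard scale
  (closed form: the cumulative hazard is linear in the common factor);
  under-5 default multipliers (6, 2, 1, 0.8, 0.6, 0.5) give the familiar
  steep neonatal-to-late-childhood decline; the 5–14 default is flat —
  the source describes no age pattern within 5–14, so the multipliers are
  a configurable free choice;
* stratified (Admin-1 × urban/rural) two-stage sampling: systematic PPS
  cluster selection within strata, a fixed number of women per cluster,
  weights = inverse inclusion probabilities; non-response is not
  simulated;
* women aged 15–49 at interview (uniform) with Poisson births over the
  months since age 15 (~3.6 expected births at the default rate of 0.0175
  births/woman-month). A stationary birth process over only the 15 years
  before interview — the simplest option — was rejected because it leaves
  periods ~20+ years back unobservable for *every* survey, contradicting
  the 24-year under-5 recall rule and destroying the characteristic
  U-shape of precision over periods; extending exposure over the
  reproductive lifespan is what makes old periods reachable only through
  older women's histories, as in real FBH data.

What it does **not** emulate — and what a green test therefore does not
establish: recall and displacement errors in reported dates, age heaping,
non-response and weight adjustments, HIV-driven survivorship bias (the
adjustment factors are exercised as arithmetic, not derived),
survey-to-survey boundary changes, or realistic fertility differentials
across areas and time.

## Calibration-test design choices

* The credible-interval calibration and closed-form-oracle checks fix the
  component variances at their generating values ("known
  hyperparameters"), making the posterior exactly Gaussian. This isolates
  the property under test — correctness of the constrained-GMRF sampler —
  from prior-vs-truth disagreement in the hyperpriors.
* The null-correlation coverage check uses observation variance 0.1 on the
  logit scale, the magnitude the package's own direct estimation produces
  on DHS-sized synthetic surveys. In this regime the posterior uncertainty
  of the draw-wise correlation dominates the finite-sample spread of the
  realized surface correlation and "the 95% interval contains 0" holds in
  ≈95% of replicates (ex-ante acceptance band [0.92, 1]: coverage of the
  point 0 is mildly conservative because shrinkage centres the posterior
  toward 0). With much smaller observation variance the interval instead
  concentrates — correctly — on the realized empirical correlation of the
  two finite surfaces, which is never exactly 0 in a single replicate.
* Simulation sizes are scaled to a single CPU: the large-sample recovery
  property runs at thousands (not 500,000) of children per area — the
  |q̂ − q| < 3·SE criterion is size-adaptive — and the U-shape property
  uses 10 replicates with shortened chains, asserting the rank property
  (the CV minimum is interior; both end periods exceed it).

## Known limitations

* The Gibbs sampler updates components one block at a time; the
  level/trend split between `μ`, `α` and `γ` mixes more slowly than a
  joint update would, which is why R̂ is computed and reported. Short
  exploratory chains can warn on split-R̂ purely from Monte-Carlo noise.
* Dense matrix algebra throughout: fine for tens of areas and a handful of
  periods (the intended scale), not for hundreds of areas.
* The two age groups are modelled independently, matching the source
  approach; a joint model of ₅q₀ and ₁₀q₅ (or their ratio) is explicitly
  out of scope.
* GeoJSON contiguity uses shared-vertex (rook-style) detection and assumes
  a common digitised topology; it is not a general polygon-intersection
  routine.
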