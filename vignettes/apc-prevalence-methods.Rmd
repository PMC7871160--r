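---
title: "Bayesian binomial age-period-cohort models for stratified prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian binomial age-period-cohort models for stratified prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Smoking prevalence observed in repeated cross-sectional surveys varies
along three entangled time axes: the age of the respondents, the survey
period, and the birth cohort. Because cohort = period − age, the three
cannot be separated by ordinary regression; an age-period-cohort (APC)
model with smoothing priors is the standard Bayesian answer. `prevapc`
fits such models to stratified prevalence count tables — the motivating
use case is smoking prevalence of men and women in urban versus
non-urban strata, observed for 5-year age groups (20-24 … 75-79) in
3-yearly survey waves (2004 … 2019) — and post-processes the posterior
into the quantities a descriptive epidemiological analysis reports:
effect-level prevalences with credible intervals, between-stratum
prevalence ratios, and directly age-standardized prevalences.

## Model

For age group $i = 1,\dots,I$ and period $j = 1,\dots,J$, the observed
smoker count is

$$y_{ij} \sim \mathrm{Binomial}(n_{ij},\, p_{ij}), \qquad
\mathrm{logit}(p_{ij}) = \eta_{ij} = \delta + \alpha_i + \beta_j +
\gamma_{k(i,j)} + z_{ij},$$

with intercept $\delta$, age effects $\alpha$, period effects $\beta$,
cohort effects $\gamma$, and a cell-level heterogeneity term $z_{ij}$
that absorbs extra-binomial variation ($z_{ij} \sim N(0, \sigma_z^2)$,
iid). The four standard submodels (age, age-period, age-cohort, APC)
toggle $\beta$ and $\gamma$; the heterogeneity term is kept in all of
them so their deviances are comparable and its posterior can be used as
a misspecification diagnostic (below).

### The unequal-interval cohort grid

Ages advance in 5-year groups while periods advance in 3-year waves, so
cohorts are indexed on a 1-year birth grid: cell $(i,j)$ maps to

$$k(i,j) = 5\,(I - i) + 3\,(j - 1) + 1,$$

where $k = 1$ is the oldest cohort (the oldest age group in the first
wave) and $k = K = 5(I-1) + 3(J-1) + 1$ the youngest. On the 12 × 6
survey lattice this gives $K = 71$ overlapping 5-year birth spans
(1925-1929, 1926-1930, …, 1995-1999). Only 63 of the 71 indices are hit
by one of the 72 cells; the 8 interior gaps are *retained* in the
parameter vector and estimated purely through the smoothing prior,
which interpolates between their observed neighbours. This convention
keeps the label arithmetic uniform and is, on this lattice, the only
one that produces 71 cohorts.

### Priors

Each included effect vector carries a first-order random-walk (RW1)
prior on its increments, e.g.
$\gamma_{k+1} - \gamma_k \sim N(0, \sigma_\gamma^2)$ over the full
$1..K$ grid including the unobserved indices. RW1 smoothing penalises
jumps but lets the data shape the curve; on gaps it behaves as a
Brownian bridge between observed neighbours. The hyperpriors are weakly
informative on the log-odds scale and exposed as arguments of
`apc_model_spec()`:

* half-normal(0, 1) on each increment SD $\sigma_\alpha, \sigma_\beta,
  \sigma_\gamma$ (`prior_scale_effects`),
* half-normal(0, 1) on $\sigma_z$ (`prior_scale_heterogeneity`),
* $N(0, 10^2)$ on $\delta$ (`prior_scale_intercept`).

Defaults of 1 on effect-increment SDs are generous: observed smoking
surfaces move by well under one log-odds unit per 1-5 year step.

### Identification

Two distinct identification devices are used, and it matters which does
what:

1. **Level.** Each effect vector is constrained to sum to zero, pushing
   the overall level into $\delta$. During sampling the first element
   of each effect is anchored at zero (a proper corner
   parameterisation); every reported draw is then deterministically
   re-centred (`center_effects()`), which changes nothing about
   $\eta_{ij}$ or the likelihood.
2. **Linear trend.** The axes satisfy cohort = period − age, so adding
   a linear trend to $\gamma$ and subtracting compensating trends from
   $\alpha, \beta$ leaves $\eta$ unchanged. This aliasing is *not*
   resolved beyond the sum-to-zero constraint and RW1 shrinkage.
   Consequently individual effect coordinates are weakly identified:
   their MCMC paths wander along the aliased direction and can show
   elevated split R-hat at practical chain lengths. Identified
   functionals — fitted cell probabilities, the intercept, second
   differences of effects — converge quickly. `check_convergence()`
   therefore accepts a parameter subset, and validation targets fitted
   probabilities rather than effect coordinates.

## Computation

`apc_fit()` builds the model for JAGS (via rjags, with the `glm`
block-sampler module loaded) and runs `chains` chains of `warmup + iter`
iterations after `adapt` adaptation steps. Defaults are 4 chains × 2000
kept with warmup equal to kept iterations; the examples and tests in
this package use 2 chains × 300-1500 kept, which on the 12 × 6 lattice
takes a few seconds per fit. All chain RNG streams are derived from the
single `seed` argument, so a fit is reproducible draw-for-draw on the
same JAGS build. Initialization failures surface as errors rather than
empty objects.

Split R-hat is computed in-package for every scalar on the centred
draws: each chain is halved and the classical between/within variance
ratio taken over the half-chains. Degenerate cases are conservative
(identical constant chains → 1; zero within-chain variance with
between-chain disagreement → ∞, a guaranteed failure). The default
failure threshold is 1.05.

### DIC

Model comparison uses the deviance information criterion with the
binomial normalising constants included, so differences between
submodels of the same table are meaningful:

$$\bar D = \mathbb{E}_{\text{post}}[-2\log L], \quad
\hat D = -2 \log L(\bar p), \quad p_D = \bar D - \hat D, \quad
\mathrm{DIC} = \bar D + p_D,$$

where the plug-in $\bar p$ is the posterior mean of the *cell
probabilities* $p_{ij}$ — not of $\eta$ or of individual effects —
because the likelihood is parameterised by $p_{ij}$ and that choice is
invariant under the sum-to-zero gauge. The identity
$\mathrm{DIC} = \hat D + 2 p_D$ holds exactly by construction and is
asserted in the tests. Because $\bar D$ is a Monte-Carlo average, DIC
carries sampling noise of a few units at short chain lengths; model
comparisons whose DIC gap is of that order need enough kept draws
(the packaged experiments use 1500/chain) or should be treated as ties,
which is itself scientifically meaningful: when the heterogeneity term
can absorb an omitted effect, submodels genuinely fit almost equally
well.

### Heterogeneity as a diagnostic

When a real effect is omitted — say, period, while the truth declines
over waves — its structure does not disappear: it is absorbed by
$z_{ij}$, whose posterior means then trend systematically along the
omitted axis instead of scattering around zero. `heterogeneity_summary()`
exposes the posterior-mean $z$ surface with per-age and per-period
means and SDs so this can be checked; the test suite verifies on
synthetic truth that an age-only fit to age-period data produces a
monotone per-period trend in $\bar z_j$ and a larger overall spread
than the well-specified fit. This mirrors how near-tied DIC values
across submodels should be interrogated in practice.

## Post-processing

* `effect_prevalence()` — per level $t$ of one axis,
  $\mathrm{expit}(\delta + \text{effect}_t)$ evaluated on every draw;
  the estimate is the posterior mean, the interval the equal-tailed
  2.5/97.5 percentile range. $z_{ij}$ is deliberately excluded: these
  are smooth effect-level summaries. On the cohort axis all $K$ levels
  are reported, with an `observed` flag for the interpolated ones.
* `prevalence_ratio()` — level-wise ratio of two strata's effect
  prevalences, conventionally non-urban / urban. The default divides
  the posterior-mean prevalences of the two independently fitted
  per-stratum models (point ratios); `type = "draws"` instead pairs
  draws and summarises the ratio distribution. The point version is the
  default because the strata are fitted independently, so draw pairing
  is arbitrary; equal-seeded fits make it reproducible but not more
  meaningful.
* `age_standardize()` — direct standardization
  $\sum_i w_i p_i$ with weights normalised to sum to one. Weights are
  always user-supplied: the household-survey weights of any given
  reference year are external data, not something the model estimates.
  The function operates identically on observed (`y/n`) and
  model-fitted prevalences.

## The synthetic-data generator

`simulate_truth()` + `simulate_prevalence_table()` emulate the survey
tables with known ground truth. The generating conditions are fixed,
survey-like defaults: the 12 × 6 lattice, constant denominators of
10,000 per cell (the order of magnitude of estimated household members
per stratum cell, and large enough that binomial noise does not swamp
effect recovery), baseline prevalence 0.35 (a men-like stratum),
an age decline of 1.5 log-odds across groups, a period decline of 0.6,
a unimodal cohort bump of 0.6 (rise then fall across birth years, as
observed smoking cohort effects do), and iid cell noise with SD 0.05.
Effect curves are deterministic parametric shapes (linear declines, a
quadratic bump) so recovery tests are reproducible and interpretable;
`curves = "rw1"` draws them from the smoothing prior instead.
`simulate_strata_pair()` produces an urban/non-urban pair whose period
declines differ by a configurable gap, emulating the headline contrast
of a faster urban decline.

What the generator does *not* emulate — and what passing recovery tests
therefore do not establish about real survey data: sampling-design
effects and nonresponse, household clustering, the noise introduced by
deriving a stratum as national-minus-urban differences, and denominator
variation across cells. The binomial-with-smooth-effects assumption is
exactly true in the synthetic world; on real data the heterogeneity
term must carry any departure from it.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` run, at sizes chosen to keep
a desk run in minutes:

* grid bookkeeping on the 12 × 6 lattice (71 cohorts, 63 observed, the
  corner cohorts and labels) — exact assertions;
* an intercept-only single-cell model checked against 1-D numerical
  quadrature of the exact posterior (agreement within 3 Monte-Carlo
  standard errors);
* parameter recovery on full-APC synthetic data (n = 10,000/cell):
  mean absolute error of fitted cell prevalences below 0.01 and 95%
  interval coverage of the true prevalences within [0.85, 0.99], with
  2 chains × 1000 kept draws;
* DIC model choice over 20 cohort-generated replicates with a strong
  cohort signal (`effect_scale = 1.5`, bump ≈ 0.9 log-odds — smaller
  than the cohort swings real smoking data show): the cohort-containing
  model must win in at least 80% of replicates;
* gauge and arithmetic invariants (sum-to-zero per draw, centring
  leaves $\eta$ unchanged, self-ratios equal one, uniform prevalence is
  a fixed point of standardization).

Absolute DIC values and absolute standardized prevalences of any
particular published analysis are *not* reproduction targets: they
depend on unpublished denominators, standard-population weights and
hyperprior choices. The procedures are validated on synthetic truth and
on qualitative patterns of the bundled tables instead.

## Numerical choices

* Counts from published percentages: `round(pct/100 * n)` half away
  from zero; at survey denominators the rounding error is negligible.
* Quantiles: R type-7 (default) percentiles for credible bounds.
* RW1 log-density: increments only; the level is fixed by the gauge
  constraint, not the prior, so `log_prior()` is a density up to a
  constant in the constrained parameterisation.
* Degenerate lattices (a single age group or period) are allowed so
  that intercept-only oracle models are expressible; step-regularity
  checks then apply only to axes with at least two levels.
* `sd` floors of 1e-3 keep generated `sigma` values positive on
  degenerate axes.

## Limitations

* The APC linear-trend indeterminacy is inherent; effect *slopes* are
  interpretable only jointly, and per-coordinate R-hat of effect
  vectors is expectedly poor in the full model. Report fitted
  probabilities, ratios at matched levels, or second differences.
* DIC near-ties are expected when the heterogeneity term is flexible;
  use `heterogeneity_summary()` before concluding that a smaller model
  suffices.
* Independent per-stratum fits mean stratum ratios carry both strata's
  aliasing choices; ratio *trends* along an axis are more stable than
  their absolute level at any single level.
* A single constant denominator per cell (fixture default) understates
  the real survey's cell-to-cell precision differences.
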