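---
title: "Modelling gender gaps in life expectancy across space and time"
author: "stgap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gender gaps in life expectancy across space and time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stgap)
```

## The problem

The gender gap in life expectancy (GGLE) — female minus male life expectancy
at birth, in years — varies strongly across countries and has followed
different trajectories over the last six decades: a rise-then-fall with a
peak in much of Europe and the Americas, a continued rise elsewhere.  A
country-year panel of GGLE is noisy, spatially correlated (neighbouring
countries share epidemiology, economy and environment) and temporally
structured.  `stgap` models such panels with a latent Gaussian
spatiotemporal regression and provides everything needed to validate the
machinery end to end on synthetic data with known ground truth.

## The model

For country $i$ and year $t$,
$$y_{it} \sim \mathrm{Normal}(\mu_{it},\ 1/\tau_e),$$
$$\mu_{it} = \alpha + s_i + \theta_t + \delta_{it} + \textstyle\sum_k \beta_k \ln x_{k,it},$$

with three nested variants: `M0s` drops the covariate sum, `M1s` is the full
global regression shown above, and `M2s` lets the two exposure coefficients
(pwPM2.5 and urbanization) differ by region, $\sum_j \beta_{1j}\ln PM_{it}$
over the six WHO regions, keeping the four confounders (poverty, female
primary education, calorie supply, smoking mortality) global.

The random effects are the standard disease-mapping building blocks:

* **Spatial, BYM2.** $s = (\sqrt{\phi}\,u^* + \sqrt{1-\phi}\,v)/\sqrt{\tau_s}$,
  where $u^*$ is an intrinsic CAR (ICAR) effect on the country adjacency
  graph — precision $Q = D - A$, sum-to-zero per connected component —
  rescaled so its geometric-mean marginal variance is 1, and $v$ is i.i.d.
  standard normal.  $\tau_s$ is then a marginal precision and
  $\phi \in [0,1]$ the share of spatially structured variance.  Isolated
  countries (islands) get a zero structured component and scaling factor 1;
  their effect is purely unstructured.
* **Temporal.** A random walk (order 1 by default, order 2 optional) with
  increment precision $\tau_\theta$, constrained to sum to zero across the
  study years so it is identified next to $\alpha$.
* **Space-time interaction.** Exchangeable (Knorr-Held Type I) i.i.d.
  $\mathrm{Normal}(0, 1/\tau_\delta)$ cells, constrained to overall zero sum.
  This matches a model governed by a single interaction precision; the
  structured interaction types (II–IV) are out of scope.

Covariates enter on the natural-log scale (they are strictly positive rates,
concentrations and supplies) and are centred before fitting, which only
shifts the intercept.  The outcome is modelled on the identity scale by
default — the literal reading of the Gaussian observation model — with an
optional log transform.

## Estimation

Estimation is Metropolis-within-Gibbs, built for auditability from scratch:

1. **Joint latent update.** Given the precisions,
   $(\alpha, \beta, s, \theta, \delta)$ is one Gaussian block.  Its full
   conditional precision is sparse (the interaction block is diagonal; the
   spatial block is a dense $n \times n$ matrix with $n \le$ a few hundred);
   we draw from it with a sparse Cholesky factorization and then project the
   draw exactly onto the sum-to-zero constraints (conditioning by kriging).
   Sampling the combined $s$ rather than $(u, v)$ separately keeps the
   latent field small; the $(u, v)$ split is recovered afterwards from its
   exact Gaussian conditional in the eigenbasis of the scaled ICAR
   generalized inverse.
2. **Conjugate precisions.** $\tau_e$, $\tau_\theta$, $\tau_\delta$ and
   $\tau_s$ have Gamma full conditionals (the BYM2 prior on $s$ has
   precision $\tau_s [\phi Q^{*-} + (1-\phi) I]^{-1}$, whose quadratic form
   and determinant are cheap in the precomputed eigenbasis).
3. **Mixing parameter.** $\phi$ takes a Metropolis step on the logit scale
   with a Robbins-Monro adapted step size targeting 30–45% acceptance,
   frozen after warm-up.
4. **Missing data.** Cells with a missing outcome but complete covariates
   are dropped from the likelihood and imputed predictively each sweep;
   cells with missing covariates are excluded entirely (never zero-filled).

Per kept draw the sampler records a pointwise Gaussian log-likelihood at
every observed cell, so DIC (Spiegelhalter plug-in form) and WAIC
(log-mean-exp pointwise density with the variance-form penalty, computed
with a stable log-sum-exp) are exact functions of the stored fit.  In
models containing the exchangeable interaction, the recorded density
integrates $\delta_{it}$ out analytically,
$y_{it} \sim \mathrm{Normal}(\mu_{it} - \delta_{it},\ 1/\tau_e + 1/\tau_\delta)$:
because $\delta$ and the observation error are exchangeable cell-level
effects (see the identifiability notes below), the conditional likelihood
scale would track their arbitrary split, whereas the marginal form depends
only on identified quantities and makes model comparison stable across
chains and seeds.

### Priors and defaults

| Parameter | Prior | Default rationale |
|---|---|---|
| $\alpha$, $\beta_k$ | Normal$(0, 1000^2)$ | effectively flat on the years scale |
| $\tau_e, \tau_\theta, \tau_\delta, \tau_s$ | Gamma$(1, 5\times10^{-5})$ | weakly informative, standard in disease mapping |
| $\phi$ | Uniform$(0, 1)$ | no prior preference for structure |

All are configurable through `modelSpec()`.  Chain defaults are 2 chains of
5,000 iterations with 2,000 warm-up; split-chain potential scale reduction
above 1.05 triggers a warning (never an error).  Equal-tailed 95% intervals
use linear-interpolation quantiles, deterministically.

### Identifiability notes

Two aliasing facts shape the numerics and the tests:

* $u^*$ is sum-to-zero per graph component, $\theta$ sums to zero over
  years, $\delta$ sums to zero overall; these projections are applied
  exactly each sweep (tolerance $10^{-10}$ in the tests) and identify
  $\alpha$.
* On a complete panel the Type-I interaction and the observation error are
  both i.i.d. cell-level Gaussians, so the likelihood identifies only
  $1/\tau_e + 1/\tau_\delta$; the split between them is driven by the
  priors, and label swaps between the two components are possible.
  Coefficient estimates and intervals are unaffected (they depend on the
  total).  The test suite therefore checks $\sigma_e^2$ against the truth
  on the interaction-free variant and the identified total on the full
  model.

## The synthetic-data generator

`simulatePanel()` composes the generative model exactly as written above,
and is first-class, tested code: every stage of the package is validated
against panels whose ground truth is known.  Defaults emulate the study
conditions of the global gender-gap analysis:

* a rectangular panel over 1960–2018 (tests and the acceptance script use
  shorter spans — 12 to 30 years — purely to keep runs desk-sized; the
  vignette states the sizes used in each place);
* fixed effects $\beta = (0.034, 0.251, -0.012, -0.061, 0.419, 0.076)$ on
  the log-covariate scale — the sign/magnitude pattern of the global GGLE
  fit, exercising realistic scales without claiming to reproduce it;
* hyperparameters $\tau_e = 150$, $\tau_s = 5$, $\phi = 0.5$,
  $\tau_\theta = 2\times10^4$, $\tau_\delta = 180$;
* strictly positive log-normal covariates with location/scale chosen to
  match published descriptive ranges (e.g. pwPM2.5 around
  $25\,\mu g/m^3$, calorie supply around $2800$ kcal/capita/day), optional
  mild positive cross-correlation through a shared factor;
* a six-region partition in contiguous blocks, standing in for the WHO
  regions;
* lattice or random-geometric stand-in geographies (the real 134-country
  adjacency is the caller's to supply as an edge list; the package never
  computes polygon contiguity, and the adjacency rule behind the published
  analysis is not stated anywhere we could find).

What the generator does **not** emulate: informative missingness (only
MCAR), measurement error in covariates, the real spatial configuration of
countries, and temporal autocorrelation in covariates (cells are
independent).  Passing tests therefore demonstrate that the machinery is
correct under the stated model, not that the model is right for any real
panel.

## Exposure aggregation

`populationWeightedMean()` implements the population-weighted exposure
statistic per zone, $\sum_i PM_i \cdot pop_i / \sum_i pop_i$, over gridded
pollutant/population/zone-mask arrays in fixed row-major order and double
precision.  Cells with positive population but missing pollutant are
excluded from numerator and denominator — the least biased choice under
missing-at-random cells — and the covered population fraction is reported;
a zone with zero covered population yields `NA` plus a warning, never a
silent zero.  Whether the published grids held population weights fixed
across years is unstated; `attachExposure()` simply joins whatever
zone-year values the caller computed.

## Trend taxonomy

`classifyTrend()` operationalizes the descriptive increase/peak/decrease
labels: smooth with a centred 5-year moving average, call the trajectory a
*peak* when the smoothed argmax sits at least 3 years inside both ends and
the raw rise and fall around it both reach 0.25 years of gap, otherwise
label by the sign of the Theil-Sen slope.  Window, margin and threshold are
explicit parameters: the original labelling rule behind the published
counts is visual/heuristic and undocumented, so this is a tunable,
reproducible stand-in, validated on clean monotone/tent shapes (100%
accuracy required) and noisy tents (≥95% over 200 replicates).

## Worked example

```{r example, eval = FALSE}
sim <- simulatePanel(simulationConfig(nCountries = 30, years = 1999:2018,
                                      seed = 1))
fit <- fitMCMC(buildModel(sim$panel, sim$graph, modelSpec("M1s")),
               nIter = 2000, nWarmup = 800, nChains = 2, seed = 1)
posteriorSummary(fit, gapCovariateNames())
overallTemporalTrend(fit)          # theta_t with 95% band
combinedSpatialEffect(fit, 2018)   # s_i + theta_t + delta_it per country
compareModels(list(
  M0s = fitMCMC(buildModel(sim$panel, sim$graph, modelSpec("M0s")),
                nIter = 2000, nWarmup = 800, nChains = 2, seed = 1),
  M1s = fit))
```

(Chunks are not evaluated at build time; the same chain is exercised by the
test suite and by `scripts/acceptance.R`, which print the actual numbers.)

## Design choices where the design was open

* **MCMC, not a deterministic approximation.**  A Gibbs sampler over the
  sparse latent field is fully implementable and auditable from first
  principles, and its conjugate blocks double as oracles in the tests.
* **RW1 trend by default.**  A "dynamic temporal trend" with a single
  precision is most simply a first-order walk; RW2 is available where extra
  smoothness is wanted.
* **Type-I interaction only.**  One interaction precision implies the
  exchangeable type; structured interaction types would need extra
  hyperparameters.
* **Identity outcome scale by default.**  The Gaussian observation model is
  read literally; a log-outcome flag exists because intercepts near 2 in
  published life-expectancy fits hint at a transformed outcome, but the
  transform is nowhere stated.
* **Edge-list adjacency input.**  Polygon contiguity is deliberately out of
  scope; any neighbourhood rule can be expressed as an edge list and
  validated by `buildGraph()`.
* **Degenerate inputs.**  Graphs may be disconnected (per-component
  scaling and constraints), panels may have missing cells (explicit
  masking/imputation policy), covariates must be strictly positive where
  observed (log transform), and ties in model ranking keep input order.

## Known limitations

* The $\tau_e$/$\tau_\delta$ split is only prior-identified (see above).
* WAIC/DIC values from short desk-scale chains carry Monte-Carlo noise of a
  few units; comparisons in the tests are therefore replicated across
  seeds.
* The sampler targets panels up to a few hundred spatial units; the dense
  $n \times n$ spatial block would need sparse treatment well beyond that.
* Absolute information-criterion values from any real reanalysis depend on
  the assembled panel, which this package deliberately does not download.
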