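---
title: "Estimating diversification dynamics from fossil occurrences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diversification dynamics from fossil occurrences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossilbd)
```

## The problem

A species-level fossil occurrence table — the kind exported by the
Paleobiology Database for groups such as reef-building corals — records,
for each identified occurrence, a taxon name and a stratigraphic age
range. From such tables, `fossilbd` estimates:

1. per-lineage times of origination (`Ts`) and extinction (`Te`), in Ma
   before present, jointly with the fossil preservation rate;
2. speciation (`lambda`) and extinction (`mu`) rates through time,
   including the number and position of rate shifts;
3. range-through diversity trajectories and discrete-bin per-capita
   rates as an independent cross-check;
4. cross-clade diversity dependence: how the (rescaled) diversity of one
   clade correlates with the speciation and extinction rates of another,
   with a horseshoe prior separating signal from noise.

All ages are in Ma before present (larger = older, present = 0); rates
are per lineage per Myr.

## Preservation models

Fossil sampling is modelled as a Poisson process along each lineage's
lifespan, conditioned on the lineage being found at least once. For a
lineage with `k` occurrences and lifespan duration `d = Ts - Te`:

* **HPP** — constant rate `q`:
  `log L = k log q - q d - log(1 - e^{-qd})`.
* **TPP** — one rate per geological epoch; the same form with the rate
  integral and occurrence counts accumulated per epoch. Epoch bins are
  closed at their older edge, and the package ships both 1-Myr uniform
  bins (`myr_bins()`) and the Cenozoic epoch table
  (`cenozoic_epochs()`).
* **NHPP** — the rate varies over the lifespan. The literature the
  preservation models descend from does not print a canonical intensity,
  so this package uses a symmetric Beta(shape, shape) profile on the
  normalized lifespan position; `shape = 1` reduces exactly to the HPP.
  This is a deliberate, documented stand-in with the correct limiting
  behaviour.

`model_test()` maximizes each model's likelihood (1, 2, and one-per-epoch
free parameters) and ranks by AICc, ties toward fewer parameters. The
epoch grid is analyst configuration, and it shapes the comparison's
error rates: AIC-type penalties admit spurious epoch structure a fixed
fraction of the time per extra parameter, so a finer grid — counter to
first intuition — *suppresses* false TPP selections by raising the
penalty while leaving genuine epoch signal (which accumulates across
lineages) easily strong enough to pay it. The validation suite uses an
8-epoch grid over a 30-Myr span for this reason.

Two numerical points matter here. First, before `Ts`/`Te` are inferred,
observed ranges stand in for lifespans. A fixed-percentage pad distorts
model selection: occurrences can then never sit near the proxy lifespan's
edges, and the Beta-shaped NHPP absorbs that artifact, winning under
*every* true regime. The package therefore extends each range by the mean
inter-occurrence gap `range/(k-1)` (the expected overhang of a uniform
sample, floored at 0.5 Myr), and scores the NHPP shape only on
occurrences interior to the observed range, rescaled to (0, 1). Given the
range endpoints, interior positions are exactly uniform under a
homogeneous process, so this statistic is immune to the range-extension
artifact while remaining sensitive to genuine lifespan-position
clustering. Second, `log(1 - e^{-x})` is evaluated with a
`log1p`/`expm1` branch at `x = log 2` so the conditioning term stays
accurate down to `qd ~ 1e-8`.

## The birth-death likelihood

For completely observed lifespans the likelihood has events at each
origination (rate `lambda(Ts_i)`), events at each extinction with
`Te_i > 0` (rate `mu(Te_i)`), and an exposure integral of
`(lambda + mu)(t) N(t)` over time, where `N(t)` counts lineages alive at
`t`. Because the integral decomposes over lineages, it is computed
exactly for piecewise-constant rates — no quadrature. Extant lineages
(`Te = 0`) contribute no extinction event; there is no conditioning on
clade survival. Estimates are therefore *conditioned on sampled
lineages*: lineages that left no fossils contribute neither events nor
exposure, which biases absolute rates somewhat below the
complete-process truth at low preservation (see "What passing tests
show" below).

### Priors and moves

Rates carry Gamma(1.1, 1) priors; the number of shifts per rate is
Poisson(`rj_poisson_mean`, default 1) with shift ages uniform over the
span. The reversible-jump moves are: rate scaling on the log scale,
shift sliding between neighbours, and birth/death of a shift. A birth
draws the new position uniformly, keeps the older segment's value and
perturbs the younger one multiplicatively (`v e^z`, `z ~ N(0, 0.7)`);
the matching death keeps the older value. The acceptance ratios carry
the order-statistics position prior and the value prior explicitly, so
the span and shift-count bookkeeping cancel correctly.

Within-model proposal scales adapt toward ~35% acceptance during the
burn-in portion of the chain only, and chains are reproducible from
their seed. A convergence report (effective sample sizes computed with
the initial-positive-sequence truncation rule) flags parameters below
ESS 200 as a warning, not a failure.

### Joint lifespan sampling

`sample_lifespans()` samples `{Ts_i, Te_i}`, the preservation
parameters, and the rate functions jointly. Conditional on the shared
parameters, lineages are independent, so `Ts` and `Te` updates run as
one vectorized independent-Metropolis sweep per generation (reflected
at the oldest/youngest occurrence), which is what makes a
200,000-generation chain on ~200 species a matter of minutes. One
generation = one full sweep plus a preservation-parameter update and one
reversible-jump update per rate.

## Trajectories and discrete-bin rates

`range_through()` counts lineages whose closed interval `[Te, Ts]`
covers each 0.1-Myr grid age (ties count as present).
`diversity_slope()` is the backwards difference, `D(t) - D(t-1)`,
reported at the younger age. `bin_occurrence_ranges()` classifies
species per 1-Myr bin into both-boundary crossers, bottom-only,
top-only, and singletons; `foote_rates()` turns these into per-capita
origination/extinction rates, with singletons excluded by construction
and `N_bt = 0` bins flagged undefined rather than erroring. Extant
species' binned ranges extend through the youngest bin.

To compare the continuous and discrete diversity curves on equal
footing, `lifespans_from_bins()` snaps each species' range to its
first/last-appearance bin edges — the resolution binned data can
actually support, and a proxy for the way inferred `Ts`/`Te` extend
beyond the observed ages. Under that convention the two paths agree
identically; the package's tests assert agreement within one species at
every bin midpoint on a high-preservation simulation.

## The multivariate birth-death model

Covariates — other clades' range-through diversity and environmental
series — enter on a common age grid, each rescaled to [0, 1] (constant
series map to zero and are flagged). Under the exponential link

`lambda(t) = lambda0 exp(sum_j gamma_lambda_j x_j(t))`,

and analogously for `mu`; the linear link uses
`lambda0 (1 + sum_j gamma_j x_j(t))` floored at `1e-5` per Myr so rates
stay valid without hidden reparameterization. Covariates are treated as
piecewise constant on their grid (an older grid point's value holds
until the next younger point). The likelihood is the same birth-death
form, accumulated cell by cell with per-cell event counts and exposures
precomputed, so one evaluation is O(cells).

Each `gamma_j` has the horseshoe prior
`gamma_j ~ N(0, psi_j^2 tau^2)` with half-Cauchy(0, 1) local (`psi_j`)
and global (`tau`) scales, sampled by the inverse-gamma auxiliary
scheme. The shrinkage weight reported per sample is
`w_j = 1 - 1/(1 + psi_j^2 tau^2)`, in [0, 1]; detection uses the
conservative rule median `w > 0.7`, with the median pooled across age
replicates. Under the prior alone, `w` piles up near 0 and 1 — the
horseshoe shape — which the tests verify.

Two design choices were genuinely open:

* **Global scale sharing.** Each rate channel (speciation, extinction)
  gets its own global scale by default. With a single shared scale, a
  real effect in one channel is shrunk by the other channel's noise:
  in the package's calibration tests, an extinction driver simulated at
  `gamma_mu = 1` earns a visibly lower median `w` under a shared scale
  than with per-channel scales, while pure-noise covariates stay far
  below the detection rule and the false-positive rate (median
  `w > 0.7` on no-effect data) stays well under 10% either way.
  `separate_global = FALSE` restores the shared-scale variant.
* **Turnover.** A covariate's effect on lineage turnover is the sum of
  its speciation and extinction effects, summarized by median and 95%
  highest-posterior-density interval. Where a multiplicative fold-change
  reading is wanted, `exp(T_j)` (covariate moving over its full [0, 1]
  range) is one plausible mapping, but it is not uniquely implied by the
  sum-of-effects definition.

The linear and exponential links are compared by posterior harmonic
means of the log-likelihoods (`harmonic_mean_logml()`, computed with
max-shift stabilization). The harmonic-mean estimator is known to be
unstable in general; it is retained here because it is the comparison
the workflow standardizes on, and the tests only rely on it to separate
links under strong, correctly-specified effects.

## The synthetic-data generator

`simulate_bd()` is an exact event-driven simulator (per-segment
exponential waiting times, redrawn at rate-segment boundaries, which the
memoryless property makes exact), not a time-stepped approximation; that
is what makes the analytic checks in the test suite valid
(`E[N(t)] = n0 e^{(lambda-mu)t}`, subcritical extinction, and so on).
Rate functions are canonicalized (equal adjacent segments merged), so a
coupled-clade simulation with zero coupling consumes the random stream
identically to the uncoupled simulation and reproduces it exactly —
a property the tests assert.

`simulate_preservation()` samples occurrence times per lineage from the
HPP/NHPP/TPP process over `[Te, Ts]` and drops unobserved lineages from
the occurrence output while keeping them in the truth table, so
preservation-induced bias is itself measurable. NHPP times are drawn
exactly (counts Poisson(`q d`), positions Beta(shape, shape)), which is
distributionally identical to thinning but exact. `bin_ages()` censors
point ages to stage bins, closed at the older edge, with an age equal to
the youngest boundary assigned to the youngest bin. Sites are assigned
by random grouping — sufficient for the co-occurrence filter, with no
spatial structure implied.

Default magnitudes emulate a reef-coral-like record at desk scale:
clade roots 12-25 Ma, speciation 0.2-0.8 and extinction 0.05-0.25 per
lineage per Myr, preservation 0.25-3 per lineage per Myr (chosen for
test power; the empirical per-epoch magnitudes are not characterized in
the source data), 1-Myr stage bins, and fifty age replicates at
production scale.

### What passing tests do and do not show

The generator draws from exactly the model family the estimators assume:
piecewise-constant rates, Poisson preservation, independent uniform age
errors within bins, and known extant status. Passing recovery tests
therefore validate the *implementation* (likelihoods, samplers,
bookkeeping), not robustness to real-data violations — taxonomic error,
spatially structured sampling, correlated age errors, or preservation
heterogeneity across lineages. One inherent property is visible even
here: at moderate preservation (`q = 1.5`) a substantial fraction of
short-lived lineages leave no fossils, and because estimates are
conditioned on sampled lineages the absolute rate posteriors sit below
the complete-process truth — most visibly for extinction, whose 95% HPD
can narrowly exclude it — while recovering the sampled subset's rates
almost exactly. This is a documented property of the method family, not
a sampler defect.

## Desk-scale versus production settings

The documented production defaults follow the workflow the package
implements: fifty age replicates, eleven species subsets, 50M/100M/25M
generation chains thinned every 25-40k, 20% burn-in. The test suite and
the acceptance script scale these down (chains of 6k-200k generations;
clades of 50-400 observed species; 1-20 replicates), sizes chosen so the
statistical assertions retain power while a full run stays in the
minutes range. The vignette's numbers quoted above (w calibration,
false-positive rate, conditioning bias) are all recomputed by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Known limitations

* No per-lineage preservation-rate heterogeneity (e.g. gamma-distributed
  `q` across lineages), no fossilized-birth-death tree inference, and no
  per-clade rate multipliers within a single run.
* The pipeline merges per-subset median `Ts`/`Te` before rate
  estimation; uncertainty removed by taking medians is not propagated
  (full replicate sets can be run through the estimators directly when
  that matters).
* Time-lagged covariate effects and covariate interactions are out of
  scope for the MBD.
* The harmonic-mean marginal likelihood is a high-variance estimator;
  link comparisons should be read qualitatively.
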