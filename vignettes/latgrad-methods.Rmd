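---
title: "Methods: latitudinal gradients of body-shape diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latitudinal gradients of body-shape diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`latgrad` implements a phylogenetic comparative pipeline for asking whether
multivariate trait diversity accumulates differently across a latitudinal
gradient: do assemblages at different latitudes differ in morphospace
occupation, and is the *rate* of trait evolution state-dependent on the
latitude band a lineage occupies? This vignette documents the models, the
tunable parameters, the synthetic-data world used by the test suite, and the
design decisions taken where the analysis recipe leaves choices open.

## The pipeline

1. **Latitude quartiles.** Species are binned by the rank of their absolute
   latitude-range centroid into four *equal-count* bins (`lower`, `second`,
   `third`, `upper`). Equal-count binning by rank (not interpolated
   percentiles) is used because only ranks can guarantee equal class sizes:
   the `n mod 4` leftover species go to the most equatorial bins, and ties
   in absolute latitude break by ascending species label, which makes the
   assignment invariant to row order. Reported breakpoints are the maximum
   absolute latitude inside each of the first three bins.

2. **Size correction.** Body size is the geometric mean of standard length,
   body width, and body depth. Each of the eight log measurements is
   regressed on log size by generalized least squares with the
   Brownian-motion (BM) covariance `C[i, j] = shared path length`; residuals
   are the size-corrected traits. Natural logs throughout. The GLS model is
   plain BM by default; a Pagel's-lambda transform is available through the
   `lambda` argument because the choice is not identified by the recipe —
   BM is the conventional default of the function family this step mirrors.

3. **Discrete history.** Quartile states evolve under an Mk model,
   optionally expanded with 1–4 hidden rate classes (ER or ARD tying inside
   each class, one shared class-switch rate). Models are fitted by maximum
   likelihood (Felsenstein pruning, multi-start bounded optimization) and
   compared by AICc / Akaike weights with `n =` number of tips. Stochastic
   character maps are drawn by backward sampling of node states from the
   pruning tables followed by endpoint-conditioned path sampling via
   uniformization; occupancy through time is the lineage-time share of each
   observed state in 1-Myr bins measured backward from the present.

4. **Morphospace.** Covariance PCA of the centered residuals; disparity
   (Procrustes-variance convention, denominator `n`, overall-mean centering)
   on all eight residual axes; convex-hull volume and minimum-spanning-tree
   functional evenness (FEve) on the first six PC axes. Pairwise group
   differences are tested by permuting quartile labels (sizes preserved)
   and comparing *absolute* differences with a strict `>` and no +1
   correction, so `p = 0` means "less than 1/n_perm"; uncertainty is
   profiled by within-group bootstrap.

5. **Rates.** Tip rates come from a random-local-clock multivariate BM
   MCMC; state dependence is assessed by a joint MCMC over the discrete
   history, background branch rates, and state multipliers `zeta` with a
   spike-and-slab indicator `delta ~ Bernoulli(0.5)` (`delta = 0` forces
   `zeta == 1` in the likelihood, so the posterior frequency of
   `delta = 1` is the posterior probability of state-dependent rates). Log
   tip rates are regressed on latitude and absolute latitude by robust
   phylogenetic M-estimation (Huber, k = 1.345, after whitening by the
   inverse Cholesky factor of the BM covariance).

## The state-dependent rate model

For trait `j` on edge `e` the Brownian increment variance is

```
prop_j * sigma2_0 * b_e * sum_segments zeta(state) * duration
```

* `sigma2_0` — global scale, trait variance per Myr; diffuse lognormal
  prior (`log sigma2_0 ~ N(0, 10)`).
* `b_e` — background multiplier from a random local clock: per-branch shift
  indicators with inclusion probability `prior_n_shifts / n_branches`
  (the 400/500/600 grid is quoted on a reference-tree scale of 6,364
  branches and rescaled proportionally for smaller trees), lognormal shift
  sizes (SD 0.5 on the log scale).
* `zeta_k` — state multipliers constrained to arithmetic mean 1 across the
  four quartiles, separating pattern from scale; a flat Dirichlet prior on
  the underlying simplex.
* `prop_j` — per-trait proportions summing to the trait count, absorbing
  among-trait rate differences; traits are otherwise independent after size
  correction (a tractable default; an estimated trait correlation matrix is
  deliberately out of scope).

Likelihoods are computed by the pruning (contrast) algorithm in compiled
code, with the GLS root value plugged in, so they equal the dense
multivariate-normal density with covariance built from shared weighted path
lengths — the property the oracle tests assert. MCMC proposals: scale moves
on `sigma2_0`, symmetric two-coordinate transfer moves on the `zeta` and
`prop` simplexes, shift birth/death and resize, indicator flips, and
redraws of the discrete history on a random subtree. A subtree redraw
proposes from the exact tip-conditional distribution of histories under the
fixed Mk parameters, so its Metropolis ratio is the trait-likelihood ratio
alone. Mk parameters stay fixed at their ML estimates inside the rate MCMC.
Chains thin to at most 10,000 stored samples; an effective-sample-size
check on `sigma2_0` raises a `low_ess` flag below 200.

**Tip rate definition.** A species' tip rate is `sigma2_0 * b_e` on its
terminal branch, *excluding* `zeta`. The recipe regresses tip rates on
latitude before the state-dependent analysis; including the state effect in
the regressed quantity would make that test circular. A flag would be easy
to add, but the default is the non-circular one.

## The synthetic world

The generator suite produces what the analysis assumes: an ultrametric
birth–death tree (forward simulation, rejection-conditioned on the tip
count, simple stopping between the n-th birth and the next event); an exact
CTMC realization of the discrete character; traits evolving by BM whose
edge variance is `branch rate x state multiplier x base rate x duration`
with i.i.d. lognormal branch rates (the uncorrelated-lognormal assumption);
allometric raw measurements (`log trait = slope * log size + BM noise`);
and a cell-by-species occurrence table keyed by 1.35-degree (about 150 km)
latitude bands.

Defaults used in the recovery studies were fixed before running them: 300
tips, ER transition rate 0.1 per Myr among quartiles, eight traits with
base rate 1, a 2x multiplier on the upper quartile, and UCLN log-SD 0.2 —
modest background heterogeneity of the kind the joint model exists to
absorb. What a green test establishes is that the machinery recovers known
parameters from data generated *under the model's own assumptions*; it does
not establish robustness to the ways real measurement data violate them
(phylogenetic error, correlated traits, biased sampling of latitudes).

## Numerical choices

* Matrix exponentials: one eigendecomposition per generator, exponentiated
  eigenvalues per branch; scaling-and-squaring with a (13,13) Padé
  approximant as fallback when reconstruction error exceeds `1e-10`.
* Uniformization dominating rate `1.05 * max |Q_ii|`; the jump-count cap
  (default 1e6) errors with the offending branch named.
* Optimizer: multi-start L-BFGS-B on log rates, bounds `[1e-9, 100]` per
  Myr; non-converged models are flagged and excluded from Akaike weights.
* Convex hulls: incremental beneath-beyond construction with tolerance
  `1e-9` times the coordinate range; affinely degenerate point sets return
  volume 0 with a warning. No qhull binding is assumed.
* Joint ancestral reconstruction ties break toward the lowest state index
  (`which.max` semantics), documented and tested on a symmetric cherry.
* Root treatment for Mk likelihoods: flat prior over expanded states by
  default, stationary distribution as an option.

## A structural rank deficiency worth knowing about

Because body size is the geometric mean of three of the eight measurements,
the GLS slopes of those three traits on log size sum to exactly 3 and their
residuals sum to exactly zero: the eight residual traits span at most seven
dimensions. The PCA therefore drops one axis (with a warning) and the
"first six axes" capture almost everything — a structural consequence of
the size proxy, not a data quirk.

## Known limitations

* The background-rate model is a random local clock, not a full UCLN per
  branch; both absorb lineage effects, but shift counts are only
  interpretable relative to the chosen prior.
* Grid cells are opaque identifiers; no geodesy or map rendering.
* Discrete-model uncertainty is not propagated into the rate MCMC
  (Mk parameters are fixed at ML estimates).
* Desk-scale MCMC settings (tens of thousands of iterations) are suitable
  for the simulation studies in the test suite; analyses of
  thousand-species trees should use the full 300,000-iteration settings
  and check the `low_ess` flag.
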