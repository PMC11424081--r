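# latgrad

Phylogenetic comparative tools for **latitudinal gradients in multivariate
trait diversification** — built for questions like: do marine fish
assemblages at high latitudes occupy morphospace differently than tropical
ones, and is body shape evolving *faster* there?

The package takes a time-calibrated phylogeny, a species × trait table of
linear measurements with latitude-range centroids, and (optionally) a
grid-cell occurrence table, and provides:

* **Latitude quartiles** — equal-count bins of absolute latitude centroids
  (rank-based; ties by species label; documented remainder rule).
* **Size correction** — body size as the geometric mean of standard length,
  body width and body depth; per-trait phylogenetic GLS residuals of
  `log trait ~ log size` under Brownian motion (`C[i,j] =` shared path
  length).
* **Discrete history** — Mk models with 1–4 hidden rate classes (ER/ARD),
  AICc/AICw model comparison, joint ancestral states, stochastic character
  maps by uniformization, and state occupancy through time in 1-Myr bins.
* **Morphospace** — covariance PCA; per-quartile disparity (Procrustes
  variance, `(1/n) Σ ||x_i − x̄||²` about the overall mean), 6-axis
  convex-hull volume, MST-based functional evenness (FEve); permutation
  p-values and bootstrap distributions; per-cell assemblage summaries.
* **Rates** — random-local-clock multivariate BM tip rates; a joint MCMC in
  which a discrete state multiplies the BM rate
  (`var_e = prop_j σ²₀ b_e Σ ζ(state) dt`), with a spike-and-slab
  state-dependence indicator `δ`; robust (Huber) phylogenetic regression of
  log tip rates on latitude.
* **Simulators** for every input (birth–death trees, CTMC histories,
  state-dependent traits, allometric measurements, occurrence tables), so
  the whole pipeline is testable offline.

## Worked example

Simulate a 200-tip world in which the upper latitude quartile doubles the
rate of body shape evolution, then recover that signal:

```r
library(latgrad)
tree  <- simulate_bd_tree(200, birth_rate = 1, death_rate = 0.2, seed = 4)
truth <- simulate_mk_history(tree, build_mk_generator("ER", 1, 0.12)$Q, seed = 54)
sim   <- simulate_traits_sdbm(tree, truth, base_sigma2 = rep(1, 8),
                              multipliers = c(1, 1, 1, 2), ucln_sd = 0.2, seed = 55)
states <- truth$tip_states
quart  <- factor(c("lower","second","third","upper")[states],
                 levels = c("lower","second","third","upper"))

round(group_disparity(sim$tips, quart), 1)
#>  lower second  third  upper
#>   40.3   41.1   31.8   55.5

fits <- fit_mk_models(tree, states, tyings = "ER", n_classes = 1:2,
                      n_starts = 3, seed = 1)
fits
#>  model       lnL k     AICc      AICw
#>   ER-1 -173.3884 1 348.7969 0.8860611
#>   ER-2 -173.3884 3 352.8992 0.1139389

maps <- sample_stochastic_maps(tree, states, fits[[1]]$model, n_maps = 200, seed = 2)
subset(occupancy_through_time(maps), state == 4 & bin_start < 3)
#>    bin_start bin_end state mean   q05  q95
#> 4          0       1     4 0.22 0.197 0.24
#> 8          1       2     4 0.19 0.112 0.26
#> 12         2       3     4 0.24 0.084 0.41

post <- musscrat_mcmc(tree, sim$tips, states, iters = 15000, seed = 3,
                      mk_model = fits[[1]]$model)
post$p_delta
#> [1] 1
subset(state_rate_ratios(post), b == 1 & a == 4)
#>    a b mean   lo   hi
#> 10 4 1 2.28 1.76 3.11
```

Reading the output: upper-quartile disparity (55.5) exceeds the other
bins; the equal-rates 1-class Mk model wins on AICc; about 22% of recent
lineage-time sits in the upper quartile; the posterior probability of
state-dependent rates is 1, and the upper/lower rate fold-difference is
estimated at 2.3 (95% CI 1.8–3.1), covering the simulated 2×.

With real data, start from files instead:

```r
m   <- match_tree_traits(load_tree("tree.nwk"), load_traits("traits.csv"))
tab <- assign_latitude_quartiles(m$table)
sc  <- size_correct_table(m$tree, tab)
pca <- run_pca(sc$residuals)
```

A small CLI covers the common steps
(`Rscript -e 'latgrad::latgrad_cli()' match --tree t.nwk --traits x.csv
--out out/`; subcommands `match`, `quartiles`, `sizecorrect`, `simulate`,
`history`, `morphospace`).

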