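# phylosoil

Phylogenetic signal in local-scale plant–soil associations.

On fully mapped forest plots with gridded soil chemistry, every species can
be assigned *soil association traits*: the median value of each soil
variable over the grid cells its stems occupy. `phylosoil` asks whether
closely related species share those associations — whether clades occupy
recognisable positions along soil gradients — and answers it at two levels:

* **Phylogeny-wide signal**: the mean absolute standardized independent
  contrast, and Blomberg's K,

  $$K = \frac{\mathrm{MSE}_0/\mathrm{MSE}}
        {[\mathrm{tr}(V) - n/(\mathbf{1}'V^{-1}\mathbf{1})]/(n-1)},$$

  each tested against tip-shuffle permutation nulls (K two-tailed, mean
  |contrast| low-tailed: conservatism means *small* contrasts).
* **Node-specific signal**: each internal node's trait mean under both
  tip averaging and ancestral (nodes-as-units) averaging, against a shared
  stream of tip-shuffle permutations, with the reporting filters used in
  community phylogenetics (significance under both averagings, per-tail
  α = 0.05 inclusive, leave-one-out exclusion of nodes that depend on
  species with fewer than 5 individuals, high-tail-only reporting for PCA
  axes).

The package is tidyverse-native (trait tables in, tibbles out, `tidy()` /
`glance()` / `autoplot()` methods), uses `ape` trees, preserves polytomies
(one rank-split contrast per multifurcation, flagged), and ships a
synthetic-data generator — pure-birth trees, Brownian species optima,
autocorrelated cross-correlated soil landscapes, clustered habitat-filtered
stem placement — so the whole pipeline can be exercised and calibrated with
known truth.

## Worked example

Simulate a 48-species, 12,000-stem plot on a 50 × 25 grid of 20 m cells
(15 soil variables, species optima evolving by Brownian motion on the tree,
stems habitat-filtered on extractable phosphorus), then run the full
analysis:

```r
library(phylosoil)
library(dplyr)

bundle <- make_scenario_bundle(
  scenario(n_species = 48, total_stems = 12000, seed = 2024)
)

res <- run_pipeline(run_config(
  tree = bundle$tree, census = bundle$census, grid = bundle$grid,
  out_dir = "results/run1", R = 999, seed = 1
))
#> [phylosoil] input: 12000 stems, 48 tips, 1250 grid cells, 15 layers
#> [phylosoil] pca: 15 variables; first 3 axes carry 81% of variance
#> [phylosoil] extract: 48 species with medians over 8 trait(s)
#> [phylosoil] match: 48 species retained; dropped 0 tips, 0 trait rows
#> [phylosoil] signal: K computed for 8 trait(s)
#> [phylosoil] node-tests: 52 node(s) pass the reporting filters across 8 trait(s)

purrr::map_dfr(res$k_results, tidy)[, c("trait", "K", "p_value", "n")]
#> # A tibble: 8 × 4
#>   trait      K p_value     n
#>   <chr>  <dbl>   <dbl> <int>
#> 1 Al    0.142    0.036    48
#> 2 Mn    0.0615   0.84     48
#> 3 P     0.221    0.002    48
#> 4 pH    0.0544   0.926    48
#> 5 slope 0.0522   0.974    48
#> 6 PCA1  0.0447   0.8      48
#> 7 PCA2  0.234    0.002    48
#> 8 PCA3  0.0363   0.518    48
```

The driver variable (P) and the axes correlated with it carry clear
phylogeny-wide signal (two-tailed permutation p = 0.002); K itself sits
well below 1 because medians of finitely many stems add non-heritable
noise to the species optima — with ecological traits it is the permutation
test, not K's magnitude, that carries the inference. Node-level results
for phosphorus, high tail:

```r
tidy(res$node_reports[["P"]]) |>
  filter(sig_high) |>
  select(species, n_species, tip_mean, anc_mean, p_high_tip, p_high_anc)
#> # A tibble: 7 × 6
#>   species                      n_species tip_mean anc_mean p_high_tip p_high_anc
#>   <chr>                            <int>    <dbl>    <dbl>      <dbl>      <dbl>
#> 1 t1, t33                              2     3.59     3.59      0.024      0.024
#> 2 t1, t33, t36                         3     3.49     3.44      0.017      0.024
#> 3 t1, t32, t33, t36                    4     3.60     3.69      0.004      0.001
#> 4 t1, t14, t15, t20, t28, t32…        10     3.19     3.29      0.001      0.002
#> 5 t1, t3, t9, t14, t15, t20, …        13     3.10     3.04      0.002      0.026
#> # ℹ 2 more rows
```

A nested family of clades around `t1, t32, t33, t36` associates with high
extractable phosphorus (tip-average means of 3.1–3.6 mg kg⁻¹ against a
plot mean of 2.87): these are clades whose species sit together on the
phosphorus-rich end of the landscape, significant under both averaging
methods. `run_pipeline()` also writes `traits.tsv`, `pca_loadings.tsv`
(variables × axes with a `% variance` footer), `k_table.tsv`,
`node_tests_{low,high}.tsv`, a long-format file of every node × trait ×
tail × method p value, and a JSON metadata sidecar; outputs are
byte-identical for the same config and seed.

Lower-level entry points (`species_medians()`, `run_pca()`,
`independent_contrasts()`, `blomberg_k()`, `node_permutation_test()`,
`filter_and_flag()`) compose with pipes; see the vignette
(`vignettes/plant-soil-signal.Rmd`) for the statistical details, the
generator's design and the package's calibration results.

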