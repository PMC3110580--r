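# traitgradient

Partitioning plant functional-trait diversity within and among communities,
and asking how that diversity evolved.

`traitgradient` is an R package for community ecologists and evolutionary
biologists working with three familiar ingredients: a plot-by-species
abundance table, individual-plant trait measurements (leaf and root
morphology, height), and a dated phylogeny of the species pool. It implements
trait-gradient analysis, phylogenetically independent contrasts, Blomberg's K
permutation tests, and Bray–Curtis/NMDS ordination as one coherent, seeded
pipeline, together with a synthetic-data generator that produces communities
with known trait structure so every stage can be tested and calibrated.

## The core model

**Trait-gradient analysis.** With `t_sp` the (log10) trait value of species
`s` in plot `p` and `a_sp` its abundance (fraction of quadrats occupied),
communities are arranged along the gradient of abundance-weighted community
mean traits

    p̄_p = Σ_s a_sp t_sp / Σ_s a_sp

and each species' mean trait value `t̄_s = Σ_p a_sp t_sp / Σ_p a_sp` is
partitioned additively into an among-community component (its mean position
along the gradient)

    β_s = Σ_p a_sp p̄_p / Σ_p a_sp

and a within-community component `α_s = t̄_s − β_s`, its trait value relative
to co-occurring species. The identity `α_s + β_s = t̄_s` holds by
construction. The intraspecific slope `b_s` (OLS slope of `t_sp` on `p̄_p`
for species measured in ≥ 3 plots) measures how fast traits shift within a
species relative to the community gradient; its expected value is 1 when
plants track the gradient fully, tested with a one-sample t-test.

**Comparative layer.** Standardized independent contrasts (Felsenstein
pruning; equal branch lengths by default, chosen via contrast diagnostics)
give through-origin evolutionary correlations `r = Σc_x c_y / √(Σc_x² Σc_y²)`
with N−1 df, reported alongside ordinary cross-species correlations.
Phylogenetic signal in each trait component is measured with Blomberg's K
(K = 1 under Brownian motion) and tested by comparing the variance of
standardized contrasts against tip-shuffled permutations.

**Ordination layer.** Bray–Curtis dissimilarities and best-of-starts Kruskal
NMDS (stress-1 × 100) summarize composition; species scores on axis 1 serve
as habitat affinities, with a Monte-Carlo stress test and plot-mean
trait-vs-axis correlations.

## Worked example

A small packaged dataset (12 species, 6 plots, generated by
`make_fixture()`) ships under `inst/extdata/fixture/`:

```r
library(traitgradient)
fx <- system.file("extdata", "fixture", package = "traitgradient")
inp <- read_inputs(file.path(fx, "tree.nwk"), file.path(fx, "community.csv"),
                   file.path(fx, "plants.csv"), file.path(fx, "plots.csv"),
                   file.path(fx, "species_constants.csv"), log10_traits = FALSE)
occ <- impute_missing_traits(inp$occ)

g <- trait_gradient(occ, "sla")
g
#> <trait_gradient> sla
#>    12 species, 6 plots
#>    among-plot variance fraction: 0.354
#>    within-species variance fraction: 0.280
#>    R2(t_bar ~ alpha) = 0.763, R2(t_bar ~ beta) = 0.330
tidy(g)
#> # A tibble: 12 x 7
#>   species n_plots t_bar  beta   alpha n_bs_plots     b_s
#> 1 sp0001        5  2.65  2.26  0.391           4  1.12
#> 2 sp0002        6  2.29  2.25  0.0385          6  0.750
#> ...
```

Here 35% of occurrence-level SLA variation lies among plots, species means
are explained mostly by the within-community component (R² = 0.76), and
`sp0001`'s SLA rises along the gradient about as fast as the community mean
does (`b_s` = 1.12).

The full pipeline — imputation, ordination, slopes, correlation matrices and
signal tests for the α, β and total components — runs in one call and can
write its publication-layout tables as CSV:

```r
res <- run_full_analysis(occ, inp$tree, n_perm = 999, n_starts = 20, seed = 1)
res
#> <tga_run> 4 trait(s); 6 plots
#>   NMDS stress 0.00; habitat affinity K = 0.512 (P = 0.615)
res$table3
#> # A tibble: 12 x 5
#>    component trait         K p_value     r2
#>  1 alpha     sla       0.929   0.264  0.763
#>  2 alpha     leaf_size 1.82    0.002  0.788
#>  3 alpha     srl       1.93    0.006  0.777
#> ...
```

On this fixture (simulated with phylogenetically conserved α components and
phylogeny-free habitat affinities) the α components of leaf size and SRL show
significant signal while habitat affinity does not (K = 0.51, P = 0.62) —
the qualitative pattern the generator is designed to produce.

`autoplot()` methods draw the trait-gradient scatter (with the 1:1 line) and
the NMDS ordination; `tidy()`/`glance()` return tibbles for further dplyr
work.

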