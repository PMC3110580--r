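---
title: "Methods: trait-gradient partitioning, phylogenetic signal, and the synthetic-data generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-gradient partitioning, phylogenetic signal, and the synthetic-data generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitgradient)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices a careful user should know about.

## 1. The trait-gradient partition

The analysis operates on an `occurrence_table()`: a plot-by-species abundance
table (abundance = fraction of quadrats occupied, in (0, 1]; percentages are
accepted and divided by 100 at ingest) plus individual-plant trait records.
All traits are log10-transformed once at ingest and every downstream
statistic works on the log scale, so "trait" below always means a log10
quantity.

Writing $t_{sp}$ for the trait value of species $s$ in plot $p$ (the mean
over individuals when several plants were collected) and $a_{sp}$ for its
abundance, the community trait gradient is the vector of abundance-weighted
plot means

$$\bar p_p = \frac{\sum_s a_{sp} t_{sp}}{\sum_s a_{sp}},$$

and each species' abundance-weighted mean $\bar t_s$ splits into an
among-community component $\beta_s$ (its mean location along the gradient)
and a within-community component $\alpha_s$ (its value relative to
co-occurring species):

$$\beta_s = \frac{\sum_p a_{sp} \bar p_p}{\sum_p a_{sp}}, \qquad
  \alpha_s = \bar t_s - \beta_s .$$

The identity $\alpha_s + \beta_s = \bar t_s$ is exact by construction; the
test suite verifies it to $10^{-10}$ on a thousand randomly generated tables,
as well as the defining property of the weighted mean,
$\sum_s a_{sp}(t_{sp} - \bar p_p) = 0$ within every plot.

Assumptions worth stating: abundances are treated as fixed weights, not
estimates; a species absent from a plot contributes nothing (absence is "no
record", not zero); and the partition is scale-dependent — it describes
variation at the grain of the sampled plots, nothing finer or coarser.

### Intraspecific slopes

For every species with *measured* (not imputed) values in at least
`min_plots` plots (default 3, matching the convention of collecting at least
three plants before fitting a within-species trend), $b_s$ is the OLS slope
of $t_{sp}$ on $\bar p_p$ over the species' occupied plots. The community
mean here includes the focal species — these are the plot means actually
plotted on a trait-gradient figure — and $b_s = 1$ means within-species
variation tracks the community gradient one-for-one. `test_bs()` runs the
two-sided one-sample t-test of the mean slope against 1. Species whose
occupied plots show no gradient variance are excluded and logged.

### Variance decompositions

`variance_partition()` reports two unweighted sum-of-squares decompositions:
occurrence-level values ($t_{sp}$) among versus within plots, and
individual-plant values within versus among species. Unweighted sums are the
default because the headline "share of trait variation within communities" is
conventionally reported as a simple percentage; an abundance-weighted variant
is available via `weighted = TRUE` for sensitivity analysis. Degenerate
inputs (all values equal) return zero fractions with a warning rather than
NaN.

### Missing measurements

When a species occurs in a plot without a usable measurement, the
package substitutes the mean of that species' measured values from other
plots *at the same site*. Two extensions cover cases that rule does not:
if the species was never measured at that site, its global mean is used and
the log entry is flagged `cross_site`; if it was never measured anywhere for
a trait, the trait stays missing and `trait_gradient()` drops the species for
that trait with a message. Every imputation is recorded
(`imputation_log()`), and imputed values never enter the $b_s$ regressions or
the within-species variance.

## 2. Comparative methods

### Branch lengths and contrasts

Contrasts are computed by Felsenstein's pruning algorithm on a rooted,
bifurcating tree. Two numerical choices matter:

* **Equal branch lengths by default.** `run_full_analysis()` transforms all
  branch lengths to 1 before contrasts and signal tests
  (`branch_lengths = "dated"` uses the tree as given). The package's
  `contrast_diagnostics()` — the correlation between absolute standardized
  contrasts and their expected SDs — is the criterion for this choice: a
  significant correlation means the branch lengths fail to standardize the
  contrasts.
* **Zero-length edges are floored at 1e-8.** Random polytomy resolution
  (`resolve_polytomies()`, seeded, zero-length insertions) keeps path lengths
  identical while producing a strictly binary tree; the floor keeps contrast
  variances positive. On a star tree this construction provably reproduces
  the ordinary centred Pearson correlation from the through-origin contrast
  correlation (verified to 1e-6 in the tests). Note that a multifurcating
  tree of $S$ species yields $S-1$ contrasts after resolution — more than a
  contrasts algorithm that collapses each multifurcation to a single
  contrast would give, so contrast counts are reported, not assumed.

PIC correlations are computed through the origin (contrast signs are
arbitrary) with degrees of freedom $N-1$; ahistorical correlations are plain
Pearson with $n-2$.

### Blomberg's K and the permutation test

`blomberg_k()` implements the variance-ratio statistic directly from the
phylogenetic covariance matrix $C$: with the GLS mean
$\hat a = (1'C^{-1}x)/(1'C^{-1}1)$,

$$K = \frac{(x-\hat a)'(x-\hat a)\,/\,(x-\hat a)'C^{-1}(x-\hat a)}
  {\left[\mathrm{tr}(C) - n/(1'C^{-1}1)\right]/(n-1)} .$$

$K = 1$ on a star phylogeny for any data (both numerator and its expectation
reduce to 1), and $K$ averages 1 under Brownian motion — the tests confirm a
mean within [0.85, 1.15] over 200 simulations on a fixed 64-tip Yule tree,
and agreement with an independent implementation to 1e-8. Significance comes
from `signal_test()`: the variance of standardized contrasts is compared with
its distribution under tip shuffling, with the add-one rank P-value
$P = (\#\{null \le obs\} + 1)/(n_{perm}+1)$, so $P$ is bounded below by
$1/(n_{perm}+1)$ and the test is exact (verified type-I error within
[0.03, 0.07] at nominal 0.05 over 500 signal-free replicates with 199
shuffles). Permutations are seeded; the same seed gives the same P. No
multiple-testing correction is applied across traits or components by
default (raw P-values are the convention for these tables); a Holm
adjustment is available in `run_full_analysis(holm = TRUE)`.

K is computed on the same (equal-branch-length) tree as the contrasts for
internal consistency; pass `branch_lengths = "dated"` for the time-calibrated
alternative.

### Node-age interpolation

`interpolate_node_ages()` implements even spacing between dated nodes: given
fixed ages for some nodes (and tips at 0), undated nodes on each path between
consecutive dated nodes are spaced evenly, processing segments from the
oldest dated ancestor downward and re-segmenting after each assignment so
ages stay monotone along every path. This is the standard way to turn a
sparsely calibrated supertree into an ultrametric tree while minimizing
variance among branch lengths. The default root age is 139 My, the scale
used throughout the package's examples.

## 3. Ordination

`bray_curtis()` and `nmds_ordination()` wrap the standard community-ecology
machinery: Kruskal non-metric MDS (global model) from `n_starts = 20`
starting configurations — the first metric-scaling, the rest random — keeping
the lowest stress, reported as stress-1 × 100. Species scores are
abundance-weighted averages of plot scores, so a single-plot species sits
exactly on its plot; axis 1 is oriented by the habitat labels when available
(increasing scores towards the second habitat level, sorted), else by
lexicographic plot order, making signs reproducible. `stress_montecarlo()`
shuffles each species' abundance vector independently across plots —
preserving every species' occupancy frequencies while destroying joint plot
structure — and ranks the observed stress among `n_runs` null stresses with
the add-one formula. This null is one defensible choice among several; it is
deliberately conservative about species-level prevalence.

## 4. The synthetic-data generator

Field datasets of this kind are rarely deposited, so the generator
(`scenario_config()`, `simulate_scenario()`) is a first-class module: it
produces communities with *known* trait structure so that every pipeline
stage has a calibration target. The default configuration emulates a
temperate-grassland survey: 76 species on a Yule tree with root at 139 My,
27 plots in 2 habitat types, abundances as occupied fractions of 10 quadrats
(so abundances live on the grid 0.1, ..., 1.0), log10-scale traits, ~2% of
species-plot trait cells unmeasured, one plant per species per plot.

The moving parts, in order:

1. **Habitat affinity** per species: a Brownian trait rank-rescaled to
   [-1, 1]; with `habitat_signal = FALSE` (the default study condition) the
   values are tip-shuffled first, which preserves the marginal distribution
   while destroying phylogenetic covariance — mirroring the permutation
   logic of the signal test itself.
2. **Assembly**: each plot draws an environment (habitat centre ±0.5, jitter
   SD 0.15) and each species occupies each quadrat independently with
   probability `detectability × exp(−(affinity − env)²/(2·breadth²))`
   (defaults 0.7 and 0.5 — wide enough niches that plots hold a few dozen
   species, as in real grassland quadrat data).
3. **Traits**: species base value = grand mean + α component (Brownian on
   the tree, SD `sigma_alpha` = 0.2, shuffled if `alpha_signal = FALSE`) +
   `beta_strength` × affinity (0.1; the trait-turnover coupling). Plants add
   a shared community-gradient shift (below) and Gaussian noise
   (`noise_sd` = 0.05). These magnitudes — a within-community SD roughly
   twice the turnover component — were chosen once so that the default
   scenario has comfortable power for the α-signal tests at 64–76 species
   while keeping habitat structure detectable in the ordination; they are
   test-power choices, not field estimates.

### What `b_s_true` means, exactly

The estimated slope $b_s$ regresses a species' values on the *realized*
community mean, and the community mean moves when every species shifts.
This creates a structural constraint worth understanding: if all species
shift by $c$ per unit of turnover gradient, the realized gradient is
$(1+c)$ times the turnover gradient and every regression slope is
$c/(1+c) < 1$. Exactly $b_s = 1$ with nonzero trait turnover is therefore
unattainable in a linear generator — full tracking amplifies the gradient
without bound. The generator consequently implements:

* `b_s_true` < 1: shift = $\frac{b}{1-b}$ × (centred turnover gradient), so
  the expected slope is exactly $b$;
* `b_s_true` = 1: shift = `plasticity` × environment, which yields slopes of
  1 when the trait's turnover coupling is zero (the gradient is then wholly
  plastic) and mildly attenuated slopes otherwise.

A second, subtler effect drives the calibration preset
(`slope_calibration_config()`): noise in the realized plot means acts as
error in the regressor, attenuating all slopes and — because every species
regresses on the *same* noisy gradient — correlating the species' slope
errors within a run. The one-sample t-test assumes independent species, so
that shared component inflates its rejection rate even when the mean slope
is unbiased. The preset therefore keeps the phylogenetic component small
(`sigma_alpha` = 0.03), the plastic gradient strong (`plasticity` = 0.8) and
the independent plant noise moderate (`noise_sd` = 0.12), at 64 species and
24 plots. Under these conditions the mean estimated slope is unbiased
(≈1.00) and the t-test rejects at close to its nominal 5%. This is also a
caution for interpreting the test on real data: with strong turnover, mean
slopes below 1 are partly structural.

### What the generator does *not* emulate

Passing tests on synthetic data show the algorithms are correct and
calibrated under the generator's assumptions; they do not certify field
behaviour. Known gaps: occupancy is independent Bernoulli per quadrat (no
spatial autocorrelation within plots); traits are generated independently of
one another (no leaf-economics correlation structure); composition varies
along a single environmental axis, so NMDS stress on synthetic communities
is far lower than the ~9 typical of real surveys and the among-plot share of
trait variance (~45%) is far higher than the few percent seen in field data,
where many uncorrelated factors blur the gradient; and abundance is exactly
quadrat frequency, with no detection error.

## 5. Problem sizes used by the tests and the acceptance script

Chosen to make the simulation-based checks statistically meaningful while
keeping a full run in minutes on one core: 1000 random tables for the
algebraic identities; exhaustive tree topologies at 4–5 tips plus random
trees at 6–8 tips for the pruning oracle; 200 Brownian replicates on a fixed
64-tip Yule tree for K calibration; 500 replicates × 199 permutations for
the type-I error of the signal test; 200 scenario replicates each for slope
recovery (b = 1 and b = 0.2) and for the α-signal/habitat-signal contrast;
99–199 randomizations for the Monte-Carlo stress tests. The acceptance
script (`scripts/acceptance.R`) derives every stream from its `--seed`
argument.

## 6. Known limitations

* Polytomy resolution is random; contrast counts (tips − 1 after resolution)
  and correlation df depend on it, though path lengths do not. The seed is
  recorded in the outputs.
* The equal-branch-length default discards divergence-time information by
  design; users with well-calibrated trees should compare
  `branch_lengths = "dated"`.
* `blomberg_k()` inverts the covariance matrix directly — fine to a few
  hundred tips, not intended for mega-trees.
* The NMDS Monte-Carlo null and the axis-orientation rule are conventions;
  both are documented and seeded, but other defensible choices exist.
* Species-level constant traits (e.g. height from a flora) participate in
  gradient partitions and comparative tests but carry no within-species
  information, so their `b_s` and within-species variance are reported as
  missing.
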