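---
title: "Models and conventions of the IL metabolite pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions of the IL metabolite pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlnet)
```

`mqtlnet` analyzes GC-MS metabolite profiles of an introgression-line (IL)
population measured against its recurrent-parent control across seasons and
tissues.  This vignette records the statistical models the package fits, the
conventions it adopts where more than one reasonable choice exists, what the
synthetic-data generator does and does not emulate, and the problem sizes at
which the test suite exercises everything.

## Normalization

Raw relative responses are positive and right-skewed.  The chain is:

1. `median_normalize()` — each response divided by the median of all
   metabolite responses in its own sample (chromatogram).  This removes
   per-injection intensity differences.  The median here is taken over the
   *annotated* metabolites only, because that is all the data model carries;
   with a few dozen annotated compounds, a strongly co-regulated block can
   contribute to its own normalizer, which mildly attenuates between-
   metabolite correlations.  With the hundreds of mass tags of a raw
   chromatogram this effect would be negligible.
2. `reference_normalize()` — each metabolite divided by the mean control
   response for that metabolite within the same (season, tissue) stratum,
   the proxy for an injection set.  The control maps to 1, so downstream
   log10 values are centered at 0 for the control.
3. `log10_transform()` before any linear modelling; fold-change displays
   use `fold_change_display()`, i.e. ratio − 1, so a ratio of 2.2 prints as
   +1.2 and the control prints as 0.

## mQTL calling

Per metabolite, a one-way fixed-effects ANOVA across all genotypes screens
at p ≤ 0.05.  Screened metabolites go to `dunnett_test()`: two-sided
many-to-one contrasts of each IL mean against the control mean with the
pooled within-group variance.  The family-wise adjusted p-value of a
contrast with statistic $t$ is $P(\max_i |T_i| \ge |t|)$ under the joint
multivariate-$t$ of all $k$ contrasts.  For balanced designs the contrast
correlation is exactly 1/2 and the probability is evaluated by an exact
double quadrature (outer: quantile-midpoint rule over the pooled-SD scale
factor $\sqrt{\chi^2_\nu/\nu}$; inner: Simpson's rule over the shared
normal factor), which testing shows agrees with independent Monte-Carlo and
`multcomp` computations to a few parts in $10^4$.  Unbalanced designs use
seeded Monte-Carlo integration over the one-factor correlation structure
$\rho_{ij} = \sqrt{n_i n_j /((n_i+n_0)(n_j+n_0))}$.

Calls are made where the Dunnett-adjusted p is at or below α/*m*.  The
Bonferroni family size *m* is an explicit parameter, defaulting to the
number of metabolites passing the screen, and the resulting critical value
is recorded as an attribute — the package does not hard-code a critical
value, because the appropriate family depends on how many tests a given
dataset actually runs.  A permissive tier (p ≤ 0.01) is reported alongside
for heat-map display; the significant calls are always a subset of it.

Cross-season sharing intersects calls on (IL, metabolite) *with consistent
direction* — direction consistency is required, since a segment that raises
a metabolite one year and lowers it the next is not one reproducible locus.
Shared calls are then confirmed by a fixed-effects two-way ANOVA
(genotype, season, genotype×season) on the IL + control subset; either a
genotype main effect or an interaction at p ≤ 0.05 confirms (a pure
interaction pattern — opposite-sign season effects — is a real genotype
signal and is flagged as such).  `map_to_segments()` treats segments as
closed cM intervals; same-metabolite, same-direction calls on segments
overlapping with positive length merge into one putative locus whose
refined interval is the group intersection (reported `NA` for overlap
chains with empty common intersection).

## Plasticity and heritability

`coefficient_of_variation()` works on the normalized pre-log scale:
CV = sd/mean per (IL, metabolite).  `bin_frequencies()` uses half-open bins
$[kw, (k+1)w)$ of width 0.1 with a right-closed last bin and an overflow
bin, so relative frequencies always sum to 1.

`broad_sense_heritability()` fits, per metabolite,

$$y_{ijkl} = M + S_i + R(S)_{j(i)} + G_k + GS_{ik} + \varepsilon_{ijkl}$$

on log10 values with all factors fixed, then converts mean squares to
variance components through their random-model expectations:
$\hat\sigma^2_{GS} = (MS_{GS}-MS_E)/r$,
$\hat\sigma^2_{G} = (MS_G-MS_{GS})/(rs)$, negatives truncated to 0, and

$$H^2 = \frac{\hat\sigma^2_G}
{\hat\sigma^2_G + \hat\sigma^2_{GS}/s + \hat\sigma^2_\varepsilon/(rs)},$$

clamped to [0, 1] — the entry-mean (genotype-mean) basis.  For unbalanced
designs the mean squares come from a type-II partition and $r$ is the
harmonic mean of the per-cell replicate counts; REML is deliberately not
used, since the estimator is defined by the mean-squares construction.

Two properties of this estimator are worth knowing when reading test
output.  First, under $\sigma^2_G = 0$ the truncation at zero leaves a
small positive mean (about 0.08 at 77 genotypes with $s=2$, $r=3$,
$\sigma^2_{GS}=0.5$, $\sigma^2_\varepsilon=1$): the null limit is *near*
zero with a positive floor of order
$E[\max(N(0,\mathrm{sd}(MS_G - MS_{GS})/(rs)), 0)]$.  Second, recovery
accuracy is judged against the entry-mean heritability of the population
actually simulated — the realized variance components of the drawn effects,
which `simulate_h2_data()` records in its `"realized"` attribute — rather
than the asymptotic parametric value; with 77 genotypes the finite-sample
spread of the drawn genotype effects is itself a visible part of the error
against the parametric value (mean absolute error ≈ 0.055 vs parametric,
≈ 0.043 vs realized truth, at the conditions above).

`factorial_anova()` runs the 1-, 2- or 3-factor fixed-effects screens
(genotype, tissue, season; dummy coding; type-II term tests), reporting
aliased terms as untestable rather than failing.

## Correlation networks

All population-level correlations are Pearson's product-moment $r$ over
genotype (IL) means — replicates are averaged first — with two-sided
p-values from the $t$ distribution on $n-2$ df.  An edge requires
$|r| \ge 0.3$ **and** $p \le 0.01$, both inclusive; negative correlations
are kept as negative-sign edges, and topology measures are sign-blind.

`network_measures()` follows the display conventions of common
network-analyzer tools: measures are computed over *non-isolated* nodes
(recorded as `n_nodes_used`; this is the convention under which a 689-edge
network on 63 connected nodes reports density 0.353 and mean degree 21.87);
average local clustering counts degree < 2 nodes as 0 (an `"exclude"`
alternative is available); the diameter of a disconnected graph is that of
the largest component, flagged by `connected = FALSE`.

`combine_tissues()` z-scores each tissue before concatenation (within-
tissue correlations are unchanged by this affine map);
`bipartite_cross_season()` tests only season-1 × season-2 pairs;
`conserved_correlations()` first synchronizes node sets (which itself
discards edges) and then keeps edges present with the same sign in every
network.

## Seed-vs-fruit topology comparison

The comparison asks whether one tissue's network is denser than another's
*beyond what its data variance explains*.  ILs of the subset tissue are
ranked by a two-sided variance-ratio F test of their average replicate
variance (log10 scale, averaged over metabolite × season cells) against the
reference tissue's average, ordered closest-to-furthest; incremental
subsets of the ranked ILs yield networks whose measures are tested by
permutation: each permutation independently shuffles every metabolite's
values across the subset's ILs (destroying between-metabolite correlation
while keeping margins), rebuilds the network, and recomputes the measures.
A permutation "meets the criterion" when the permuted reference-minus-
subset difference is at most the observed difference — equivalently, when
the permuted measure is at least the observed subset measure — and
$p = \max(\mathrm{count}, 1)/B$, floored at $1/B$.  The opposite direction
is reported alongside (`p_opposite`) so the one-sidedness is explicit.
Shuffling IL rows jointly would preserve all correlations and provide no
null, so the per-metabolite shuffle is the only workable reading.

Inside this module, measures are computed over the **full** node set with
the strict all-pairs diameter — infinite for a disconnected graph.  This
convention is what makes the two limiting outcomes interpretable: shuffled
data produce only threshold-level spurious edges, so their density, degree
and clustering sit below any structured network's (p at the 1/B floor),
while their fragmented graphs have infinite diameter, so the diameter
criterion is met in every permutation (p = 1).  The display-convention
measures of `network_measures()` are intentionally different; the
comparison needs observed and permuted networks on one commensurable
footing, which dropping isolated nodes would break.

Modularity significance uses two nulls, both seeded: `Q` of a predefined
two-community membership against uniform permutations of the membership
vector (default $B = 10^5$), and fast-greedy maximal `Q` against
degree-preserving edge rewiring with $10|E|$ swaps per replicate (default
$B = 10^4$; an Erdős–Rényi null with matched node and edge counts is
available behind a flag, but rewiring is the default because it holds the
degree sequence — the first-order driver of modularity — fixed).

## The synthetic-data generator

`generate_population()` draws log10 responses as

$$\log_{10} y = \text{baseline}_m + \delta_{g,m} + \text{season}_{s,m}
  + u_{g,m} + w_{g,s,m} + e$$

where $\delta$ are the sparse planted effects (the truth table), $u$ is a
season-stable polygenic genotype effect (SD `genotype_sd`, control at 0),
$w$ a genotype×season wobble (SD `interaction_sd`), and $e$ the replicate
residual (SD `residual_sd`).  $u$, $w$ and $e$ all share one block
correlation matrix built from per-compound-class targets
(`build_class_covariance()`, PSD-checked and repaired by eigenvalue
clipping if a user spec is mildly indefinite), so IL-mean correlations
converge to the block targets at any replicate number.  Key defaults, each
chosen once:

* 76 ILs + control, 64 seed metabolites (2016 pairs) over seasons I/II, or
  86 fruit metabolites (3655 pairs) over three seasons; 6 replicates.
* `residual_sd = 0.08` log10 units ≈ 20% CV, typical GC-MS replicate
  scatter; `interaction_sd = 0.05`; `genotype_sd = 0.2`.
* Within-class correlation targets 0.45–0.5 (amino acids 0.5, giving a
  mean amino-acid pair correlation near 0.53 once the submodule is
  included), between-class 0.2; the six-member submodule (Gly, Ser, Thr,
  Ile, Val, Pro) at 0.87.  The submodule additionally receives
  *coordinated* planted effects — a shared fold change per chosen IL
  across all six members — emulating co-localization of the group onto
  shared QTL, which is what sustains exceptional pairwise correlations in
  the presence of large planted effects elsewhere.
* 40 planted effects drawn log-uniform over 0.25×–8×; the fruit-like
  scenario drops the submodule and weakens targets (within 0.45, between
  0.05), which yields roughly 10% vs 34% significant pairs at the standard
  thresholds — a dense/sparse contrast.
* Traits: 35 columns, 70% loading negatively on the amino-acid latent
  factor (per-genotype mean of standardized amino-acid levels) with
  magnitudes 0.3–0.9 and unit-scaled noise of SD 0.7.

`scenario_mqtl_recovery()` zeroes `genotype_sd` and `interaction_sd` and
plants exactly 20 twofold effects, so the truth table is the only genotype
signal — the setting in which caller sensitivity and false positives are
scored.  `null_population()` removes all structure (diagonal covariance),
for calibration tests.

What the generator does **not** emulate: unannotated mass tags and
injection-batch drift (so normalization is exercised only on annotated,
batch-clean data); missing measurements; heavier-than-lognormal tails; and
realistic heritability levels — with a season-stable polygenic effect of SD
0.2 over a residual of 0.08, the default population is considerably more
heritable (H² ≈ 0.95) than typical field metabolite data.  Passing tests
therefore demonstrate correctness of the machinery under a known truth, not
that real field data would yield any particular biological result.

## Problem sizes and numerical choices

The test suite runs the full recovery experiment at the study scale (77
genotypes × 64 metabolites × 6 replicates), the permutation calibration at
200 runs × B = 200, the topology comparison at B = 1000 over subset sizes
15–25, 50, 76, heritability recovery at 200 simulations, and the Dunnett
family-wise error check at 500 null families — sizes chosen so the whole
suite completes in a few minutes while keeping Monte-Carlo standard errors
well inside the asserted bands.  Empirical p-values are floored at 1/B;
Dunnett quadrature uses a 513-point Simpson grid over ±8.5 and 64 (256 when
df < 100) outer nodes; PSD repair tolerance is 1e−8; all simulations and
permutation streams take explicit integer seeds and restore the caller's
RNG state (`with_seed()`).
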