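---
title: "Total-evidence parsimony with continuous traits: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total-evidence parsimony with continuous traits: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`totem` implements a complete desk-scale pipeline for total-evidence
phylogenetics where the morphological partition is a matrix of *continuous*
traits — typically latent feature vectors extracted from specimen images by a
deep metric-learning model, averaged per genus — and the molecular partition
is a set of aligned gene fragments with incomplete taxon coverage.  Inference
is by maximum parsimony; trees are evaluated against a reference phylogeny
with two topology-only metrics; individual traits are scored for
phylogenetic signal; and a synthetic-data generator provides a controlled
stand-in for the image-derived and database inputs so every stage can be
validated end to end.

# The parsimony model

## Molecular characters

Nucleotide columns are scored with the Fitch two-pass set algorithm for
unordered states: states are bitmasks over $\{A, C, G, T\}$, IUPAC ambiguity
codes expand to their state sets, and both `?` and `-` are treated as full
ambiguity by default (the TNT-like convention for trimmed alignments;
`gap_as_state = TRUE` switches to a fifth state).  The score of a column is
the minimum number of state changes over the unrooted topology, computed on
an arbitrary rooting; it is root-invariant, which the tests assert.

## Continuous characters

A continuous trait is scored by Farris interval optimization under linear
(Manhattan) cost: each leaf carries the degenerate interval $[v, v]$
(missing values are unbounded intervals), child intervals are intersected
where they overlap, and where they are disjoint the gap between them is
added to the tree length.  For binary trees this attains the minimum total
absolute change over all real-valued assignments to internal nodes; the
tests check it against a brute-force oracle that enumerates internal
assignments over the leaf-value set (optimal $L_1$ solutions occur at data
points).

## Commensurability: the continuous weight

The single most consequential unstated parameter of the emulated protocol is
how continuous characters are weighted relative to nucleotide columns.
`totem` makes the choice explicit: every trait is linearly rescaled to
$[0, 1]$ over the observed taxa before scoring, so one trait traversing its
full observed range costs exactly one step, like one extra change in a
nucleotide column; `continuous_weight` (default 1 per rescaled column) then
scales the whole continuous partition.  `continuous_weight = 0` provably
reduces total-evidence runs to molecular-only runs (asserted in the tests).
No claim of bit-compatibility with any external parsimony program is made.

## Tree search

Each replicate draws a random taxon addition order, inserts each taxon at
the score-minimizing edge (stepwise addition), and then applies TBR branch
swapping — every bisection of the tree, reconnected across every edge pair —
accepting strictly better trees (first improvement, sweep restart) and
retaining equally parsimonious trees up to `hold_per_replicate`.  Replicates
are pooled and all trees attaining the pooled best score are returned;
`strict_consensus()` summarizes them.  Monophyly constraints (genus groups)
are enforced at both stages by rejecting candidate insertions and
reconnections that break them; an explicit-clade form is also accepted, and
overlapping non-nested clades are rejected as infeasible.

The configuration defaults (`search_config()`: 100 replicates, hold 100,
bootstrap 100/10) mirror the emulated search protocol.  The analysis
scripts and the acceptance path run with 2 addition replicates: on the
synthetic matrices used there (12–20 taxa), the heuristic already matches
the exhaustive optimum on every tractable fixture (all 105 topologies at
n = 6 and 945 at n = 7 are enumerated in the tests), so the extra
replicates buy nothing at desk scale.  This scales search effort only —
never generator parameters or test thresholds.

Genus-level trait vectors are broadcast to every species terminal of the
genus in species-level supermatrices.  With genus monophyly enforced,
identical within-genus values contribute zero extra length inside the genus
clade, so the genus-level scoring intent is preserved; after the search the
species tree is collapsed to one leaf per genus for comparison.  Whether
molecular-only runs also enforce the constraints is an open point in the
emulated protocol; the default here (`constrain_genera = NULL`) enforces
them only in total-evidence mode with species-level data, and a flag
overrides either way.

# Tree comparison

Two topology-only metrics are computed after pruning both trees to their
shared leaves (minus any explicit exclusions, e.g. genera lacking molecular
data in a gene subset):

* **Normalized Robinson–Foulds**: bipartitions unique to either tree divided
  by the total bipartition count of both.  The denominator uses the *actual*
  counts, not $2(n-3)$, so polytomous consensus trees are compared fairly.
* **Normalized align score (nAS)**: bipartitions of the two trees are
  matched one-to-one to maximize total similarity, where the similarity of
  two bipartitions is the better of the two side-pairings, each scored by
  the smaller intersection-over-union of the paired sides.  The matching is
  solved exactly as an assignment problem (weighted bipartite matching via
  igraph; a brute-force enumeration oracle checks it in the tests).  With
  matched similarity total $S$ and $U$ the larger of the two bipartition
  counts, the score is $1 - S/U$: 0 for identical binary trees, 1 when no
  edge pair has positive similarity.

Choosing $U = \max$ of the two counts (rather than $\min$) penalizes
resolution mismatch symmetrically and keeps the identical-tree zero; the
exact normalization constant of the emulated study is not printed anywhere,
so reproduction of its absolute nAS values is not claimed, and
`upper_bound = "min"` is available.  Five-run summaries report mean, median
and a 95% Student-t half-width ($t_{0.975, n-1}\, s/\sqrt{n}$), reported as
`NA` for a single run.

# Phylogenetic signal (Cmean)

For trait values $y_1, \dots, y_N$ along the tree's ordered leaf list,

$$C_{mean}(y) = 1 - \frac{\sum_{i=1}^{N-1} (y_{i+1} - y_i)^2}
                         {2 \sum_{i=1}^{N} y_i^2}.$$

Three choices deserve explanation:

* **Summation bounds.** As printed in the emulated source the bounds are
  internally inconsistent (the numerator would reference $y_{N+1}$, the
  denominator $N + 1$ values); the implementation uses the only coherent
  reading — $N$ values, $N - 1$ adjacent differences, denominator over all
  $N$ values.
* **Standardization.** The raw statistic is location-dependent (shifting all
  values changes it).  By default each trait is z-scored across leaves
  (population s.d.) before evaluation, making the statistic affine-invariant;
  `standardize = FALSE` evaluates the literal formula.
* **Leaf order.** "Ordered list of leaves" is taken as the tree's tip order
  as written (left-to-right in its newick, `tip_order()`), ladderization is
  never applied implicitly.  The order-dependence of the statistic is real
  and asserted in the tests.

Significance is a one-sided permutation test shuffling values across leaves;
with the default 999 permutations the smallest attainable p is
$1/1000 = 0.001$.  Under an i.i.d. null the p-values are uniform (checked by
a KS test) and the permutation mean of the statistic is exactly 0 — not the
$-1/(N-1)$ a lag-1 autocorrelation would give, because the boundary terms
$z_1^2 + z_N^2$ in the telescoped numerator cancel the adjacent-product
expectation; the test suite asserts the enumerated exact value.

# The synthetic world

The generator emulates the statistical structure of the real inputs:

| Parameter | Default | Meaning |
|---|---|---|
| `n_genera` | 20 | leaves of the Yule reference tree (unit height) |
| `n_traits` | 128 | latent dimensionality of the trait vectors |
| `bm_rate` ($\sigma^2$) | 1 | Brownian variance per unit branch length |
| `noise_sd` ($\tau$) | 0 | i.i.d. leaf noise; $\sigma^2=0$ gives pure noise |
| `specimens_per_genus` | 5 | replicates averaged per genus |
| `within_genus_sd` | 0.25 | specimen scatter around the genus mean |
| `genes` | 7 fragments | name, length, Jukes–Cantor rate per gene |
| `missing_fraction` | 0.2 | per-gene fraction of taxa removed |

Traits evolve independently by Brownian motion from root value 0 (the
emulated traits are explicitly not constrained to be independent; a
trait-correlation hook is the natural extension), specimens add Gaussian
scatter and are averaged per genus, and genes evolve under Jukes–Cantor
with per-gene rates, masked by uniform random per-gene taxon removal under
a coverage guarantee (every taxon keeps at least one gene).  Signal
strength is the single abstraction: $\sigma^2$ versus $\tau$ spans the
best-case/realistic/worst-case regimes the analysis scripts use.

What the generator does *not* emulate — and hence what a green test does
not establish: rate heterogeneity across sites and lineages, alignment and
trimming artefacts, base-composition bias, taxonomically structured (rather
than uniform) missingness, and correlated traits.  One practical
consequence, documented in `analysis/01_simulate.R`: model-true sequences
on a clean tree are so informative that realistic fragment lengths saturate
the molecular signal at 20 taxa; the analysis therefore simulates *short,
shallow* fragments (roughly 0.5–3 expected changes per internal edge in
total) so that the molecular tree is informative but imperfect — the regime
the total-evidence question is about.

Random baselines use uniform random labelled binary topologies (sequential
random attachment), the least-assuming reading of "randomly generated
trees"; the Yule generator is available where a birth-process shape is
wanted.  The stand-in reference for the published-baseline check is a Yule
tree on 44 genera, *synthetic* and labelled as such: the deposited
reference phylogeny is not reachable offline, and the baseline nAS in
particular is sensitive to the reference tree's shape, so that check's
margin is thin by construction.

# Numerical choices and degenerate inputs

* Scores are compared with an absolute epsilon of $10^{-9}$ when pooling
  equally parsimonious trees (continuous lengths are sums of small
  rescaled differences).
* Ties in stepwise insertion take the first-found best edge; tie retention
  during TBR is first-found up to `hold`, deduplicated by bipartition
  signature — deterministic under a fixed seed.
* Constant continuous columns rescale to all-zero (they can contribute no
  length); zero-variance traits are an *error* for Cmean, whose
  standardization is undefined there.
* Every stochastic operation takes an explicit integer seed; multi-run
  experiments use seeds `0..k-1`, and internal seed streams are derived by
  seeded sampling so nested operations never share a stream.
* Trees with fewer than four leaves have no non-trivial bipartitions; the
  metrics refuse leaf sets smaller than four after pruning.

# Known limitations

* TBR is evaluated by full rescoring of each candidate; fine into the tens
  of taxa, not engineered for hundreds.  No implied weighting, ratchet or
  sectorial searches.
* Fitch/Farris folding over polytomies is exact for the binary trees the
  search produces; scoring user-supplied polytomous trees uses sequential
  folding, an upper bound.
* No branch-length estimation and no likelihood/Bayesian inference — the
  continuous-data setting that motivates parsimony here is exactly the one
  mainstream Bayesian tools do not yet support with missing data.
* Bootstrap resampling includes the continuous partition by default
  (`resample_continuous = FALSE` reproduces the molecular-only-resampling
  reading; the emulated protocol does not say which was used).
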