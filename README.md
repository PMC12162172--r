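# totem — total-evidence parsimony with continuous morphological traits

`totem` is an R package plus analysis workflow for a question at the border
of museum digitization and statistical phylogenetics: **do continuous
morphological traits extracted from specimen images carry enough
phylogenetic signal to improve molecular phylogenies when both are analysed
together?**  It is aimed at systematists and methods researchers who want to
run, probe, or stress-test that kind of total-evidence analysis without a
GPU or a licensed parsimony program in the loop.

## What it implements

* **Maximum parsimony with mixed characters.** Fitch set-scoring for
  nucleotide columns (bitmask states, IUPAC ambiguity, `?`/`-` as missing)
  and Farris interval optimization for continuous characters under linear
  cost: for a trait with leaf values $y$, the tree length is the minimum of
  $\sum_{(u,v) \in E} |x_u - x_v|$ over all real assignments $x$ to internal
  nodes.  Traits are min–max rescaled to $[0,1]$ so one trait's full range
  costs one step, with an explicit `continuous_weight`.
* **Constrained heuristic search.** Random addition sequences + TBR branch
  swapping, genus-monophyly constraints, equally parsimonious tree
  retention, strict (Nelsen) consensus, and partition-respecting bootstrap.
* **Tree comparison.** Normalized Robinson–Foulds
  $\mathrm{nRF} = (u_1 + u_2)/(c_1 + c_2)$ on unshared bipartitions, and the
  normalized align score $\mathrm{nAS} = 1 - S/\max(c_1, c_2)$, where $S$ is
  the exactly-solved maximum-weight one-to-one matching of bipartitions
  under an intersection-over-union edge similarity (0 = identical, 1 =
  nothing matches).
* **Per-trait phylogenetic signal.** An Abouheif-style autocorrelation
  statistic along the tree's ordered leaf list,
  $C_{mean}(y) = 1 - \sum_i (y_{i+1}-y_i)^2 / (2\sum_i y_i^2)$ on z-scored
  values, with a one-sided permutation test (999 permutations, p-floor
  0.001) and threshold summaries (share of traits with $p<0.05$ and
  $C_{mean} > 0.3/0.5/0.7$).
* **Experiments.** Morphology-only / molecular-only / total-evidence runs
  with multi-seed Student-t summaries, gene ablations over all $2^k - 1$
  subsets with best-subset-per-size extraction, and uniform random-tree
  baselines.
* **Synthetic data.** Yule reference trees, Brownian-motion traits with
  tunable signal ($\sigma^2$) versus i.i.d. noise ($\tau$), per-specimen
  replicates with genus averaging, Jukes–Cantor gene fragments, and
  per-gene missing-taxon masks with a coverage guarantee.

See `vignettes/total-evidence-parsimony.Rmd` for the models, the parameter
choices and their rationale, and known limitations.

## Worked example

Two short gene fragments with 25% missing taxa per gene, plus 128 noisy
Brownian traits, on a 12-genus simulated reference:

```r
library(totem)

ds <- simulate_dataset(simulation_config(
  n_genera = 12, n_traits = 128, bm_rate = 1, noise_sd = 0.5,
  genes = data.frame(name = c("g28S", "COI"), length = c(100L, 80L),
                     rate = c(0.02, 0.06)),
  missing_fraction = 0.25, seed = 42))
ref <- ds$reference_topology

mol <- run_experiment("molecular", ref, genes = ds$genes,
                      seeds = 0:4, n_replicates = 2)
te  <- run_experiment("total_evidence", ref, traits = ds$traits,
                      genes = ds$genes, seeds = 0:4, n_replicates = 2)
rb  <- random_baseline(ref, n_trees = 5, seed = 0)
```

This prints:

```
experiment_result: mode=molecular, genes=[g28S,COI], 5 runs
  nAS 0.536 +/- 0.029 (median 0.526) | nRF 0.768 +/- 0.266 (median 0.867)
experiment_result: mode=total_evidence, genes=[g28S,COI], 5 runs
  nAS 0.074 +/- 0.000 (median 0.074) | nRF 0.111 +/- 0.000 (median 0.111)
random baseline: nAS 0.607 | nRF 1.000
```

Reading: 180 bp of shallow sequence alone is barely better than a random
tree (nAS 0.54 vs 0.61; lower is better, 0 = identical to the reference).
Adding the noisy-but-signal-bearing traits pulls the strict consensus to
nAS 0.074 — the total-evidence effect the package exists to study.  The
same traits quantified per trait:

```r
signal_table(ds$traits, ref, n_permutations = 999, seed = 0)$summary
#   n_traits mean_cmean cmean_half_width_95    mean_p max_cmean max_cmean_p
# 1      128  0.2990518          0.05151766 0.2284766 0.8333734       0.001
#   pct_gt_0.3 pct_gt_0.5 pct_gt_0.7
# 1       37.5    26.5625     7.8125
```

so 37.5% of traits have a significantly strong signal ($C_{mean} > 0.3$,
$p < 0.05$), the strongest trait reaching 0.83 at the permutation floor
p = 0.001.

## Analysis workflow

Numbered drivers under `analysis/` rebuild the study end to end on
synthetic data, writing tables to `results/`:

| Script | What it does |
|---|---|
| `01_simulate.R` | three trait regimes (pure signal / noisy / pure noise) on a shared 20-genus tree, seven short gene fragments, 30% missingness |
| `02_morphology.R` | morphology-only inference per regime + random baseline |
| `03_signal.R` | per-trait Cmean tables and threshold summaries |
| `04_total_evidence.R` | molecular-only vs total evidence per regime |
| `05_ablation.R` | gene ablation over 4 genes, best subset per size |

Run them in order from the repository root with `Rscript`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main end-to-end pipeline from scratch under the
given seed — simulating a 15-genus dataset, running all three inference
modes, the random baseline and the signal table — logging the headline
numbers to stderr and writing the JSON summary to `--out`.
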