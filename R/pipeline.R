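# End-to-end experiment orchestration: morphology-only, molecular-only
# and total-evidence runs, gene ablations, and random-tree baselines.

#' Run one phylogenetic-inference experiment
#'
#' Builds the supermatrix for the requested mode, runs the constrained
#' parsimony analysis once per seed, collapses species-level trees to
#' genus level when a genus map is given, compares every run's strict
#' consensus to the reference (excluding genera lacking molecular data in
#' the gene set used), and summarizes across runs.
#'
#' Genus-level traits are broadcast to every species terminal of the
#' genus; with genus monophyly enforced this adds no length inside the
#' genus clade, so scoring matches the genus-level intent.
#'
#' @param mode One of `"morphology"`, `"molecular"`, `"total_evidence"`.
#' @param reference Reference `phylo` (genus-level) for comparison.
#' @param traits Optional genus-level `trait_matrix`.
#' @param genes List of `gene_alignment` objects (possibly empty).
#' @param genus_map Optional named character vector species -> genus for
#'   species-level molecular data.
#' @param seeds Integer vector of per-run seeds (default `0:4`, the
#'   "5 runs" protocol).
#' @param n_replicates,hold_per_replicate Search effort per run; the
#'   defaults (10/10) are scaled down from the full 100/100 protocol for
#'   desk-scale synthetic data.
#' @param continuous_weight Weight of the continuous partition.
#' @param constrain_genera Enforce genus monophyly during search?  Default:
#'   only in total-evidence mode with species-level molecular data.
#' @param upper_bound Normalization bound for the align score.
#' @return List of class `experiment_result`: `mode`, `gene_subset`,
#'   `seeds`, `runs` (per-run data frame), `nRF`, `nAS` (score
#'   summaries), `config`.
#' @export
run_experiment <- function(mode = c("morphology", "molecular", "total_evidence"),
                           reference, traits = NULL, genes = list(),
                           genus_map = NULL, seeds = 0:4,
                           n_replicates = 10L, hold_per_replicate = 10L,
                           continuous_weight = 1,
                           constrain_genera = NULL, upper_bound = "max") {
  mode <- match.arg(mode)
  if (mode != "molecular" && is.null(traits))
    stopf("run_experiment: mode '%s' requires traits", mode)
  if (mode != "morphology" && !length(genes))
    stopf("run_experiment: mode '%s' requires at least one gene", mode)
  use_genes <- if (mode == "morphology") list() else genes
  use_traits <- if (mode == "molecular") NULL else traits
  species_level <- !is.null(genus_map)
  if (!is.null(use_traits) && species_level && length(use_genes)) {
    mol_taxa <- unique(unlist(lapply(use_genes, function(g) g$taxa)))
    bad <- setdiff(mol_taxa, names(genus_map))
    if (length(bad))
      stopf("run_experiment: taxa missing from genus map: %s",
            paste(bad, collapse = ", "))
    # broadcast genus trait vectors to species terminals
    sp_traits <- use_traits[genus_map[mol_taxa], , drop = FALSE]
    rownames(sp_traits) <- mol_taxa
    extra_genera <- setdiff(rownames(use_traits), genus_map[mol_taxa])
    use_traits <- trait_matrix(rbind(sp_traits,
                                     use_traits[extra_genera, , drop = FALSE]),
                               taxa = c(mol_taxa, extra_genera))
  }
  sm <- concatenate(use_genes, traits = use_traits)
  enc <- encode_supermatrix(sm, continuous_weight = continuous_weight)
  if (is.null(constrain_genera))
    constrain_genera <- mode == "total_evidence" && species_level
  constraints <- NULL
  if (constrain_genera && species_level) {
    constraints <- genus_map[intersect(names(genus_map), sm$taxa)]
    singles <- setdiff(sm$taxa, names(constraints))
    if (length(singles))  # genus-level terminals constrain themselves
      constraints <- c(constraints, stats::setNames(singles, singles))
  }
  mol_taxa <- unique(unlist(lapply(use_genes, function(g) g$taxa)))
  mol_genera <- if (species_level) unique(unname(genus_map[mol_taxa]))
                else mol_taxa
  runs <- lapply(seeds, function(s) {
    cfg <- search_config(n_replicates = n_replicates,
                         hold_per_replicate = hold_per_replicate,
                         seed = s, constraints = constraints,
                         continuous_weight = continuous_weight)
    ana <- parsimony_analysis(enc, cfg)
    tree <- ana$consensus
    if (species_level) {
      grp <- genus_map[tree$tip.label]
      grp[is.na(grp)] <- tree$tip.label[is.na(grp)]
      tree <- collapse_groups(tree, grp)
    }
    exclude <- if (mode == "morphology") character(0)
               else setdiff(tree$tip.label, mol_genera)
    cmp <- compare_to_reference(tree, reference, exclude = exclude,
                                upper_bound = upper_bound)
    list(seed = s, best_score = ana$best_score, n_best = ana$n_best,
         nRF = cmp$nRF, nAS = cmp$nAS,
         n_leaves_compared = length(cmp$leaves_compared),
         consensus = tree)
  })
  run_df <- data.frame(seed = vapply(runs, `[[`, 0, "seed"),
                       best_score = vapply(runs, `[[`, 0, "best_score"),
                       n_best = vapply(runs, `[[`, 0, "n_best"),
                       nRF = vapply(runs, `[[`, 0, "nRF"),
                       nAS = vapply(runs, `[[`, 0, "nAS"),
                       n_leaves_compared =
                         vapply(runs, `[[`, 0, "n_leaves_compared"))
  structure(list(mode = mode,
                 gene_subset = vapply(use_genes, function(g) g$gene, ""),
                 seeds = seeds, runs = run_df,
                 trees = lapply(runs, `[[`, "consensus"),
                 nRF = summarize_runs(run_df$nRF),
                 nAS = summarize_runs(run_df$nAS),
                 config = list(n_replicates = n_replicates,
                               hold_per_replicate = hold_per_replicate,
                               continuous_weight = continuous_weight,
                               constrain_genera = constrain_genera,
                               upper_bound = upper_bound)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: mode=%s, genes=[%s], %d runs\n",
              x$mode, paste(x$gene_subset, collapse = ","),
              nrow(x$runs)))
  cat(sprintf("  nAS %.3f +/- %.3f (median %.3f) | nRF %.3f +/- %.3f (median %.3f)\n",
              x$nAS$mean, x$nAS$half_width_95, x$nAS$median,
              x$nRF$mean, x$nRF$half_width_95, x$nRF$median))
  invisible(x)
}

#' Enumerate all non-empty gene subsets
#'
#' All `2^k - 1` non-empty subsets in canonical order: by size, then
#' lexicographically.  Seven genes give 127 subsets.
#'
#' @param gene_names Character vector of gene names (>= 1).
#' @return List of character vectors.
#' @export
enumerate_gene_subsets <- function(gene_names) {
  gene_names <- as.character(gene_names)
  if (!length(gene_names)) stopf("enumerate_gene_subsets: no genes")
  out <- list()
  for (k in seq_along(gene_names)) {
    combos <- utils::combn(sort(gene_names), k, simplify = FALSE)
    keys <- vapply(combos, paste, "", collapse = "\r")
    out <- c(out, combos[order(keys)])
  }
  out
}

#' Gene-ablation study
#'
#' Runs molecular-only (and, when traits are given, total-evidence)
#' experiments for every gene subset; comparisons exclude genera lacking
#' molecular data in that subset.  Also extracts the best subset per
#' size by mean nAS (ties broken by mean nRF, then lexicographically).
#'
#' @inheritParams run_experiment
#' @param sizes Optional subset sizes to restrict to.
#' @param ... Passed to [run_experiment()] (seeds, search effort, ...).
#' @return List with `results` (long data frame) and `best_per_size`.
#' @export
gene_ablation <- function(reference, genes, traits = NULL, genus_map = NULL,
                          sizes = NULL, ...) {
  if (!length(genes)) stopf("gene_ablation: need at least one gene")
  subsets <- enumerate_gene_subsets(vapply(genes, function(g) g$gene, ""))
  if (!is.null(sizes))
    subsets <- Filter(function(s) length(s) %in% sizes, subsets)
  modes <- c("molecular", if (!is.null(traits)) "total_evidence")
  rows <- list()
  for (sub in subsets) {
    gs <- subset_genes(genes, sub)
    for (mode in modes) {
      res <- run_experiment(mode, reference,
                            traits = if (mode == "total_evidence") traits,
                            genes = gs, genus_map = genus_map, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(subset = paste(sort(sub), collapse = "+"),
                   size = length(sub), mode = mode,
                   nAS_mean = res$nAS$mean, nAS_hw = res$nAS$half_width_95,
                   nAS_median = res$nAS$median,
                   nRF_mean = res$nRF$mean, nRF_hw = res$nRF$half_width_95,
                   nRF_median = res$nRF$median,
                   n_runs = res$nAS$n_runs, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(results, results[c("mode", "size")]),
                                function(d) {
    d <- d[order(d$nAS_mean, d$nRF_mean, d$subset), , drop = FALSE]
    d[1L, , drop = FALSE]
  }))
  rownames(best) <- NULL
  list(results = results, best_per_size = best[order(best$mode, best$size), ])
}

#' Random-tree baseline scores against a reference
#'
#' Draws uniform random binary trees on the reference leaf set, compares
#' each to the reference, and summarizes both metrics with 95% t-CIs --
#' the "randomly generated trees of this size" baseline.
#'
#' @param reference A `phylo` object (>= 4 leaves).
#' @param n_trees Number of random trees (default 5).
#' @param seed Integer seed.
#' @param upper_bound Passed to [normalized_align_score()].
#' @return List with `nRF`, `nAS` (score summaries) and `values` (per-tree
#'   data frame).
#' @export
random_baseline <- function(reference, n_trees = 5L, seed = 0L,
                            upper_bound = "max") {
  seeds <- derive_seeds(seed, n_trees)
  vals <- lapply(seeds, function(s) {
    rt <- random_binary_tree(reference$tip.label, seed = s)
    cmp <- compare_to_reference(rt, reference, upper_bound = upper_bound)
    c(nRF = cmp$nRF, nAS = cmp$nAS)
  })
  df <- as.data.frame(do.call(rbind, vals))
  list(nRF = summarize_runs(df$nRF), nAS = summarize_runs(df$nAS),
       values = df)
}
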