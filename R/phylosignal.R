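# Per-trait phylogenetic-signal quantification: an Abouheif-style Cmean
# autocorrelation statistic on trait values along the tree's ordered leaf
# list, with a permutation significance test.

#' Cmean phylogenetic-signal statistic of a trait vector
#'
#' For trait values `y_1..y_N` ordered by the tree's leaf list,
#' `Cmean = 1 - sum_{i=1}^{N-1} (y_{i+1} - y_i)^2 / (2 * sum_i y_i^2)`.
#' Values are z-scored across leaves (population standard deviation)
#' before evaluation unless `standardize = FALSE`, making the statistic
#' location- and scale-invariant; higher values indicate stronger
#' phylogenetic signal (adjacent leaves having similar values).
#'
#' @param y Numeric vector of trait values in leaf order (length >= 3).
#' @param standardize Z-score the values first? Default `TRUE`; `FALSE`
#'   evaluates the literal formula on raw values.
#' @return Real number `<= 1`.
#' @examples
#' cmean(c(1, 1, -1, -1))   #  0.5
#' cmean(c(1, -1, 1, -1))   # -0.5
#' @export
cmean <- function(y, standardize = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3L) stopf("cmean: need at least 3 values")
  if (any(is.na(y))) stopf("cmean: missing values not supported")
  if (standardize) {
    s <- sqrt(mean((y - mean(y))^2))
    if (s == 0) stopf("cmean: zero-variance trait")
    y <- (y - mean(y)) / s
  } else if (all(y == 0)) stopf("cmean: all-zero trait")
  1 - sum(diff(y)^2) / (2 * sum(y^2))
}

#' Permutation test for Cmean
#'
#' Shuffles trait values across leaves uniformly at random and reports
#' `p = (1 + #permutations with Cmean >= observed) / (1 + n_permutations)`.
#' With the default 999 permutations the smallest attainable p-value is
#' 0.001.
#'
#' @inheritParams cmean
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `cmean`, `p_value`, `n_permutations`.
#' @export
cmean_permutation_p <- function(y, n_permutations = 999L, seed = 0L,
                                standardize = TRUE) {
  obs <- cmean(y, standardize = standardize)
  n <- length(y)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i)
      cmean(y[sample.int(n)], standardize = standardize), 0)
  })
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_permutations)
  list(cmean = obs, p_value = p, n_permutations = as.integer(n_permutations))
}

#' Leaf order of a tree as written
#'
#' The left-to-right tip sequence of the tree's newick representation
#' (cladewise traversal order); this is the "ordered list of leaves" the
#' Cmean statistic runs along.
#'
#' @param tree A `phylo` object.
#' @return Character vector of leaf labels in written order.
#' @export
tip_order <- function(tree) {
  phy <- stats::reorder(tree)
  n <- length(phy$tip.label)
  phy$tip.label[phy$edge[phy$edge[, 2] <= n, 2]]
}

#' Per-trait phylogenetic signal table with aggregates
#'
#' Computes Cmean and its permutation p-value for every trait, ordering
#' values by the tree's leaf list as written (left-to-right tip order of
#' the newick).  Aggregates mirror a per-model summary row: average Cmean
#' with 95% t-CI, average p, maximum Cmean with its p, and the percentage
#' of traits with `p < 0.05` and Cmean above each threshold.
#'
#' @param traits A `trait_matrix` whose taxa equal the tree's leaves.
#' @param tree A `phylo` object supplying the leaf order.
#' @param n_permutations,seed,standardize Passed to
#'   [cmean_permutation_p()].
#' @param thresholds Cmean thresholds for the percentage columns
#'   (default `c(0.3, 0.5, 0.7)`).
#' @return List with `per_trait` (data frame: trait, cmean, p_value) and
#'   `summary` (one-row data frame).
#' @export
signal_table <- function(traits, tree, n_permutations = 999L, seed = 0L,
                         standardize = TRUE, thresholds = c(0.3, 0.5, 0.7)) {
  labs <- tip_order(tree)
  if (!setequal(rownames(traits), labs))
    stopf("signal_table: trait taxa and tree leaves differ: %s",
          paste(c(setdiff(rownames(traits), labs),
                  setdiff(labs, rownames(traits))), collapse = ", "))
  m <- traits[labs, , drop = FALSE]
  seeds <- derive_seeds(seed, ncol(m))
  res <- lapply(seq_len(ncol(m)), function(j)
    cmean_permutation_p(m[, j], n_permutations = n_permutations,
                        seed = seeds[j], standardize = standardize))
  per_trait <- data.frame(trait = colnames(m),
                          cmean = vapply(res, `[[`, 0, "cmean"),
                          p_value = vapply(res, `[[`, 0, "p_value"),
                          stringsAsFactors = FALSE)
  cm <- per_trait$cmean; pv <- per_trait$p_value
  ci <- summarize_runs(cm)
  imax <- which.max(cm)
  pct <- vapply(thresholds, function(th)
    100 * mean(pv < 0.05 & cm > th), 0)
  summary <- data.frame(n_traits = ncol(m),
                        mean_cmean = ci$mean, cmean_half_width_95 = ci$half_width_95,
                        mean_p = mean(pv),
                        max_cmean = cm[imax], max_cmean_p = pv[imax])
  for (k in seq_along(thresholds))
    summary[[sprintf("pct_gt_%g", thresholds[k])]] <- pct[k]
  list(per_trait = per_trait, summary = summary)
}
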