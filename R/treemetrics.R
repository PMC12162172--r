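# Quantitative tree comparison against a reference phylogeny.

#' Normalized Robinson-Foulds distance
#'
#' Number of bipartitions unique to either tree divided by the total
#' bipartition count of both trees.  Polytomous trees (e.g. consensus
#' trees) are compared fairly: the denominator uses each tree's actual
#' bipartition count, not `2(n-3)`.
#'
#' @param t1,t2 `phylo` objects on identical leaf sets (>= 4 leaves).
#' @return Real in `[0, 1]`; 0 iff the bipartition sets are identical.
#' @examples
#' normalized_rf(parse_newick("((A,B),C,(D,E));"),
#'               parse_newick("((A,C),B,(D,E));"))  # 0.5
#' @export
normalized_rf <- function(t1, t2) {
  check_same_leaves(t1, t2)
  k1 <- split_keys(t1); k2 <- split_keys(t2)
  denom <- length(k1) + length(k2)
  if (denom == 0L) return(0)
  shared <- sum(k1 %in% k2)
  (length(k1) + length(k2) - 2L * shared) / denom
}

check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stopf("leaf sets differ: %s",
          paste(c(setdiff(t1$tip.label, t2$tip.label),
                  setdiff(t2$tip.label, t1$tip.label)), collapse = ", "))
  if (length(t1$tip.label) < 4L)
    stopf("tree comparison needs at least 4 shared leaves")
  invisible(TRUE)
}

#' Edge-matching similarity of two bipartitions
#'
#' The best of the two side-pairings, each scored by the smaller of the
#' two intersection-over-union values; 1 iff the bipartitions are
#' identical.
#'
#' @param b1,b2 [bipartition] objects over the same leaf universe.
#' @return Real in `[0, 1]`.
#' @export
align_similarity <- function(b1, b2) {
  u1 <- c(b1$side_a, b1$side_b); u2 <- c(b2$side_a, b2$side_b)
  if (!setequal(u1, u2))
    stopf("align_similarity: bipartitions over different leaf universes")
  iou <- function(a, b) {
    length(intersect(a, b)) / length(union(a, b))
  }
  pairing <- function(a1, bb1, a2, bb2) min(iou(a1, a2), iou(bb1, bb2))
  max(pairing(b1$side_a, b1$side_b, b2$side_a, b2$side_b),
      pairing(b1$side_a, b1$side_b, b2$side_b, b2$side_a))
}

# Similarity matrix between two split lists (anchor-free sides + universe).
split_similarity_matrix <- function(sides1, sides2, labels) {
  n <- length(labels)
  m <- matrix(0, length(sides1), length(sides2))
  for (i in seq_along(sides1)) {
    s1 <- sides1[[i]]; c1 <- setdiff(labels, s1)
    for (j in seq_along(sides2)) {
      s2 <- sides2[[j]]; c2 <- setdiff(labels, s2)
      iou_ss <- length(intersect(s1, s2)) / length(union(s1, s2))
      iou_cc <- length(intersect(c1, c2)) / length(union(c1, c2))
      iou_sc <- length(intersect(s1, c2)) / length(union(s1, c2))
      iou_cs <- length(intersect(c1, s2)) / length(union(c1, s2))
      m[i, j] <- max(min(iou_ss, iou_cc), min(iou_sc, iou_cs))
    }
  }
  m
}

# Exact maximum-weight one-to-one matching value for a non-negative
# similarity matrix (assignment problem), via weighted bipartite matching.
max_weight_matching_value <- function(sim) {
  pos <- which(sim > 0, arr.ind = TRUE)
  if (!nrow(pos)) return(0)
  n1 <- nrow(sim); n2 <- ncol(sim)
  edges <- cbind(pos[, 1L], n1 + pos[, 2L])
  g <- igraph::make_graph(t(edges), n = n1 + n2, directed = FALSE)
  types <- c(rep(FALSE, n1), rep(TRUE, n2))
  m <- igraph::max_bipartite_match(g, types = types,
                                   weights = sim[pos])
  m$matching_weight
}

#' Normalized align score between two trees
#'
#' Bipartitions of the two trees are matched one-to-one to maximize the
#' total [align_similarity()] (the assignment problem, solved exactly);
#' the matched similarity total `S` is normalized by the upper bound of
#' matched edges `U = max` of the two bipartition counts, and the score is
#' `1 - S/U`: 0 for identical binary trees, 1 when no pair of edges has
#' positive similarity.
#'
#' @param t1,t2 `phylo` objects on identical leaf sets (>= 4 leaves).
#' @param upper_bound `"max"` (default) or `"min"`: which of the two
#'   bipartition counts normalizes the matching total.
#' @return Real in `[0, 1]`.
#' @examples
#' normalized_align_score(parse_newick("((A,B),C,(D,E));"),
#'                        parse_newick("((A,C),B,(D,E));"))  # 1/3
#' @export
normalized_align_score <- function(t1, t2, upper_bound = c("max", "min")) {
  check_same_leaves(t1, t2)
  upper_bound <- match.arg(upper_bound)
  s1 <- split_sides(t1); s2 <- split_sides(t2)
  u <- if (upper_bound == "max") max(length(s1), length(s2))
       else min(length(s1), length(s2))
  if (u == 0L) return(0)
  sim <- split_similarity_matrix(s1, s2, t1$tip.label)
  1 - max_weight_matching_value(sim) / u
}

#' Compare a tree to a reference phylogeny
#'
#' Both trees are pruned to their shared leaves minus `exclude` (e.g.
#' genera lacking molecular data in a gene subset), then both metrics are
#' computed.
#'
#' @param tree,reference `phylo` objects.
#' @param exclude Leaf labels to drop before comparison.
#' @param upper_bound Passed to [normalized_align_score()].
#' @return List with `nRF`, `nAS`, `leaves_compared`, `pruned`,
#'   `upper_bound`.
#' @export
compare_to_reference <- function(tree, reference, exclude = character(0),
                                 upper_bound = "max") {
  shared <- setdiff(intersect(tree$tip.label, reference$tip.label), exclude)
  if (length(shared) < 4L)
    stopf("compare_to_reference: fewer than 4 shared leaves after exclusion")
  pruned <- unique(c(setdiff(tree$tip.label, shared),
                     setdiff(reference$tip.label, shared)))
  t1 <- if (length(shared) < length(tree$tip.label))
    prune_to(tree, shared) else tree
  t2 <- if (length(shared) < length(reference$tip.label))
    prune_to(reference, shared) else reference
  list(nRF = normalized_rf(t1, t2),
       nAS = normalized_align_score(t1, t2, upper_bound = upper_bound),
       leaves_compared = sort(shared), pruned = sort(pruned),
       upper_bound = upper_bound)
}

#' Summarize repeated runs of a score
#'
#' Mean, median and the 95% Student-t confidence half-width
#' (`t[0.975, n-1] * sd / sqrt(n)`); with a single value the half-width is
#' reported as `NA`.
#'
#' @param values Numeric vector (length >= 1).
#' @return List with `mean`, `half_width_95`, `median`, `n_runs`.
#' @examples
#' summarize_runs(c(0.1, 0.2, 0.3, 0.4, 0.5))  # half-width ~ 0.196
#' @export
summarize_runs <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) stopf("summarize_runs: empty input")
  hw <- if (n == 1L) NA_real_ else {
    s <- stats::sd(values)
    if (s == 0) 0 else stats::qt(0.975, n - 1L) * s / sqrt(n)
  }
  list(mean = mean(values), half_width_95 = hw,
       median = stats::median(values), n_runs = n)
}
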