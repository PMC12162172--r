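#' Parse a newick string into a phylogenetic tree
#'
#' Trees are handled as unrooted throughout the package: root placement in
#' the input is retained for display but ignored by all scoring and
#' comparison functions.  Branch lengths are tolerated on input and
#' dropped; leaf labels are whitespace-trimmed and must be unique.
#'
#' @param text A newick string (must end with `;`).
#' @return An [ape::phylo] object without branch lengths.
#' @examples
#' tr <- parse_newick("(A,B,(C,D));")
#' leaf_labels(tr)
#' @export
parse_newick <- function(text) {
  if (length(text) != 1L || !is.character(text) || !nzchar(trimws(text)))
    stopf("newick parse error: empty input")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stopf("newick parse error: unbalanced ')' at position %d", i)
  }
  if (depth != 0L)
    stopf("newick parse error: %d unclosed '(' at end of input", depth)
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) || inherits(phy, "multiPhylo"))
    stopf("newick parse error: malformed tree '%s'", text)
  phy$tip.label <- trimws(phy$tip.label)
  if (any(!nzchar(phy$tip.label)))
    stopf("newick parse error: empty leaf label")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stopf("newick parse error: duplicate leaf label(s): %s",
          paste(dup, collapse = ", "))
  phy$edge.length <- NULL
  phy$node.label <- NULL
  phy
}

#' Write a tree as newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL` the newick string is returned.
#' @return The newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Leaf labels of a tree
#' @param tree A `phylo` object.
#' @return Character vector of leaf labels.
#' @export
leaf_labels <- function(tree) tree$tip.label

#' Construct a canonical bipartition
#'
#' A bipartition (split) is the pair of leaf sets induced by removing an
#' edge from an unrooted tree.  The canonical orientation puts the
#' lexicographically smallest label in `side_a`; both sides are sorted.
#'
#' @param side_a,side_b Disjoint character vectors of leaf labels.
#' @return An object of class `bipartition` with fields `side_a`, `side_b`.
#' @export
bipartition <- function(side_a, side_b) {
  side_a <- sort(unique(as.character(side_a)))
  side_b <- sort(unique(as.character(side_b)))
  if (length(intersect(side_a, side_b)))
    stopf("bipartition sides overlap: %s",
          paste(intersect(side_a, side_b), collapse = ", "))
  if (!length(side_a) || !length(side_b))
    stopf("bipartition sides must be non-empty")
  if (min(side_b) < min(side_a)) { tmp <- side_a; side_a <- side_b; side_b <- tmp }
  structure(list(side_a = side_a, side_b = side_b), class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat(sprintf("{%s} | {%s}\n", paste(x$side_a, collapse = ","),
              paste(x$side_b, collapse = ",")))
  invisible(x)
}

# Internal: non-trivial splits as a list of character vectors, each the
# sorted side *not* containing the lexicographically smallest leaf.
split_sides <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) return(list())
  phy <- ape::unroot(ape::collapse.singles(tree))
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  anchor <- min(labs)
  root_id <- length(labs) + 1L  # ape convention: first internal node is root
  out <- list()
  for (i in seq_along(pp)) {
    node <- i + length(labs)
    if (node == root_id) next
    s <- labs[pp[[i]]]
    if (length(s) < 2L || n - length(s) < 2L) next
    if (anchor %in% s) s <- setdiff(labs, s)
    out[[length(out) + 1L]] <- sort(s)
  }
  unique(out)
}

split_keys <- function(tree) {
  vapply(split_sides(tree), paste, "", collapse = "\r")
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted topology; trees with
#' fewer than four leaves have none.
#'
#' @param tree A `phylo` object.
#' @return A list of [bipartition] objects.
#' @examples
#' length(bipartitions(parse_newick("((A,B),(C,D));")))  # 1
#' @export
bipartitions <- function(tree) {
  labs <- tree$tip.label
  lapply(split_sides(tree), function(s) bipartition(setdiff(labs, s), s))
}

#' Uniform random labelled binary tree
#'
#' Draws an unrooted binary topology uniformly at random over all labelled
#' topologies (proportional-to-distinguishable-arrangements model), by
#' sequential random attachment: each leaf after the third subdivides a
#' uniformly chosen edge.
#'
#' @param leaf_labels Character vector of distinct labels (at least 3).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A `phylo` object.
#' @export
random_binary_tree <- function(leaf_labels, seed) {
  leaf_labels <- as.character(leaf_labels)
  if (anyDuplicated(leaf_labels))
    stopf("duplicate leaf labels: %s",
          paste(unique(leaf_labels[duplicated(leaf_labels)]), collapse = ", "))
  if (length(leaf_labels) < 3L) stopf("need at least 3 labels")
  ut <- with_seed(seed, utree_random(leaf_labels))
  phylo_from_utree(ut)
}

#' Strict (Nelsen) consensus of trees
#'
#' Returns the tree containing exactly the bipartitions present in every
#' input tree.  All inputs must share the same leaf set.
#'
#' @param trees A non-empty list of `phylo` objects on identical leaf sets.
#' @return A `phylo` object (possibly polytomous).
#' @export
strict_consensus <- function(trees) {
  if (!length(trees)) stopf("strict_consensus: empty tree list")
  labs <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    li <- sort(trees[[i]]$tip.label)
    if (!identical(li, labs)) {
      d <- c(setdiff(li, labs), setdiff(labs, li))
      stopf("strict_consensus: leaf sets differ (symmetric difference: %s)",
            paste(sort(unique(d)), collapse = ", "))
    }
  }
  sides <- split_sides(trees[[1]])
  keys <- vapply(sides, paste, "", collapse = "\r")
  keep <- rep(TRUE, length(sides))
  for (tr in trees[-1]) {
    k2 <- split_keys(tr)
    keep <- keep & keys %in% k2
  }
  tree_from_splits(trees[[1]]$tip.label, sides[keep])
}

# Build a tree (rooted representation, unrooted semantics) from mutually
# compatible anchor-free split sides.
tree_from_splits <- function(labels, sides) {
  sides <- unique(sides)
  nwk_of <- function(cluster) {
    subs <- Filter(function(s) length(s) < length(cluster) && all(s %in% cluster),
                   sides)
    maximal <- Filter(function(s) {
      !any(vapply(subs, function(t)
        length(t) > length(s) && all(s %in% t), TRUE))
    }, subs)
    covered <- unique(unlist(maximal))
    loose <- setdiff(cluster, covered)
    parts <- c(loose, vapply(maximal, nwk_of, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(nwk_of(sort(labels)), ";")
  parse_newick(txt)
}

#' Prune a tree to a subset of leaves
#'
#' Restricts the topology to `keep`, suppressing degree-2 nodes.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain (at least 3).
#' @return A `phylo` object on `keep`.
#' @export
prune_to <- function(tree, keep) {
  keep <- as.character(keep)
  bad <- setdiff(keep, tree$tip.label)
  if (length(bad))
    stopf("prune_to: labels not in tree: %s", paste(bad, collapse = ", "))
  if (length(keep) < 3L) stopf("prune_to: need at least 3 leaves to keep")
  ape::keep.tip(tree, keep)
}

#' Check monophyly of leaf groups on an unrooted tree
#'
#' A group is monophyletic when some edge of the unrooted tree separates
#' exactly that group from the rest; singleton groups (and groups covering
#' all, or all but one, leaves) are trivially monophyletic.
#'
#' @param tree A `phylo` object.
#' @param groups Named character vector mapping each leaf label to a group.
#' @return Named logical vector, one entry per group.
#' @export
check_monophyly <- function(tree, groups) {
  labs <- tree$tip.label
  missing <- setdiff(labs, names(groups))
  if (length(missing))
    stopf("check_monophyly: unassigned leaves: %s",
          paste(missing, collapse = ", "))
  groups <- groups[labs]
  n <- length(labs)
  keys <- split_keys(tree)
  anchor <- min(labs)
  out <- vapply(unique(groups), function(g) {
    members <- sort(labs[groups == g])
    k <- length(members)
    if (k <= 1L || k >= n - 1L) return(TRUE)
    side <- if (anchor %in% members) sort(setdiff(labs, members)) else members
    paste(side, collapse = "\r") %in% keys
  }, TRUE)
  names(out) <- unique(groups)
  out
}

#' Collapse monophyletic groups to single leaves
#'
#' Replaces each (monophyletic) group's clade by a single leaf labelled by
#' the group name; the result is the induced topology on the groups.
#'
#' @inheritParams check_monophyly
#' @return A `phylo` object with one leaf per group.
#' @export
collapse_groups <- function(tree, groups) {
  mono <- check_monophyly(tree, groups)
  if (any(!mono))
    stopf("collapse_groups: group(s) not monophyletic: %s",
          paste(names(mono)[!mono], collapse = ", "))
  labs <- tree$tip.label
  groups <- groups[labs]
  reps <- labs[!duplicated(groups)]
  if (length(reps) < 2L) stopf("collapse_groups: need at least 2 groups")
  out <- ape::keep.tip(tree, reps)
  out$tip.label <- unname(groups[out$tip.label])
  out
}
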