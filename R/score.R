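# Parsimony scoring on the internal unrooted representation.
#
# Fitch two-pass set scoring for unordered molecular states and Farris
# interval optimization (Manhattan/linear cost) for continuous characters,
# both evaluated in one postorder sweep over all columns at once.
# Polytomies are folded child-by-child (exact for binary trees, which is
# all the search produces).

# tipdata: list(mol = int matrix tips x Cm, lo/hi = numeric tips x Cc, w)
# rows are ordered by utree tip id.
score_utree <- function(ut, tipdata, root_tip = 1L) {
  po <- utree_postorder(ut, root_tip)
  n_tip <- ut$n_tip
  has_mol <- !is.null(tipdata$mol) && ncol(tipdata$mol)
  has_cont <- !is.null(tipdata$lo) && ncol(tipdata$lo)
  mol_states <- vector("list", length(ut$nbr))
  lo_states <- vector("list", length(ut$nbr))
  hi_states <- vector("list", length(ut$nbr))
  mol_cost <- 0L
  cont_cost <- 0
  for (v in po$post) {
    if (v <= n_tip) {
      if (has_mol) mol_states[[v]] <- tipdata$mol[v, ]
      if (has_cont) { lo_states[[v]] <- tipdata$lo[v, ]; hi_states[[v]] <- tipdata$hi[v, ] }
      next
    }
    kids <- po$children[[v]]
    if (has_mol) {
      s <- mol_states[[kids[1L]]]
      for (k in kids[-1L]) {
        sk <- mol_states[[k]]
        a <- bitwAnd(s, sk)
        z <- a == 0L
        if (any(z)) {
          mol_cost <- mol_cost + sum(z)
          a[z] <- bitwOr(s, sk)[z]
        }
        s <- a
      }
      mol_states[[v]] <- s
    }
    if (has_cont) {
      lo <- lo_states[[kids[1L]]]; hi <- hi_states[[kids[1L]]]
      for (k in kids[-1L]) {
        L <- pmax(lo, lo_states[[k]]); H <- pmin(hi, hi_states[[k]])
        gap <- L - H
        pos <- gap > 0
        if (any(pos)) {
          cont_cost <- cont_cost + sum(gap[pos])
          tmp <- L[pos]; L[pos] <- H[pos]; H[pos] <- tmp
        }
        lo <- L; hi <- H
      }
      lo_states[[v]] <- lo; hi_states[[v]] <- hi
    }
  }
  # fold in the root tip against its neighbour's state
  s0 <- po$start
  if (has_mol) {
    a <- bitwAnd(mol_states[[s0]], tipdata$mol[root_tip, ])
    mol_cost <- mol_cost + sum(a == 0L)
  }
  if (has_cont) {
    gap <- pmax(lo_states[[s0]], tipdata$lo[root_tip, ]) -
      pmin(hi_states[[s0]], tipdata$hi[root_tip, ])
    cont_cost <- cont_cost + sum(gap[gap > 0])
  }
  mol_cost + tipdata$w * cont_cost
}

#' Fitch parsimony length of a single molecular column
#'
#' Minimum number of unordered state changes on the tree, computed by the
#' two-pass set algorithm on an arbitrary rooting (root-invariant).
#' Missing data (`?`, `-`, `N`) count as full ambiguity.
#'
#' @param tree A `phylo` object.
#' @param column Named character vector of states (names = leaf labels),
#'   or named integer bitmasks over A=1, C=2, G=4, T=8.
#' @return Non-negative integer.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' fitch_length(tr, c(A = "A", B = "A", C = "C", D = "C"))  # 1
#' @export
fitch_length <- function(tree, column) {
  ut <- utree_from_phylo(tree)
  states <- column[ut$labels]
  if (is.character(states)) states <- encode_bases(states)
  states[is.na(states)] <- 15L
  td <- list(mol = matrix(as.integer(states), ncol = 1L), lo = NULL, hi = NULL,
             w = 0)
  as.integer(score_utree(ut, td))
}

#' Farris continuous parsimony length of a single trait
#'
#' Minimum total absolute change over all real-valued assignments to
#' internal nodes (linear cost), computed by interval (Farris)
#' optimization.  Missing values are unbounded intervals.
#'
#' @param tree A `phylo` object.
#' @param column Named numeric vector of trait values (`NA` = missing), or
#'   a two-column matrix of interval bounds with row names.
#' @return Non-negative real.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' farris_continuous_length(tr, c(A = 0, B = 0, C = 1, D = 1))  # 1
#' @export
farris_continuous_length <- function(tree, column) {
  ut <- utree_from_phylo(tree)
  if (is.matrix(column)) {
    lo <- column[ut$labels, 1L]; hi <- column[ut$labels, 2L]
  } else {
    v <- column[ut$labels]
    lo <- ifelse(is.na(v), -Inf, v); hi <- ifelse(is.na(v), Inf, v)
  }
  td <- list(mol = NULL, lo = matrix(lo, ncol = 1L), hi = matrix(hi, ncol = 1L),
             w = 1)
  score_utree(ut, td)
}

#' Total parsimony score of a tree against an encoded matrix
#'
#' Sum over molecular columns of the Fitch length plus
#' `continuous_weight` times the summed Farris lengths of the (rescaled)
#' continuous columns.
#'
#' @param tree A `phylo` object whose leaves match the matrix taxa.
#' @param matrix An `encoded_matrix` (see [encode_supermatrix()]).
#' @return Non-negative real.
#' @export
tree_score <- function(tree, matrix) {
  stopifnot(inherits(matrix, "encoded_matrix"))
  if (!setequal(tree$tip.label, matrix$taxa))
    stopf("tree_score: tree leaves and matrix taxa differ: %s",
          paste(c(setdiff(tree$tip.label, matrix$taxa),
                  setdiff(matrix$taxa, tree$tip.label)), collapse = ", "))
  ut <- utree_from_phylo(tree)
  score_utree(ut, encoded_for_labels(matrix, ut$labels))
}
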