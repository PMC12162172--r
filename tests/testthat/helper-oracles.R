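# Independent brute-force oracles and fixture builders used across the
# suite.  These deliberately avoid the package's own scoring/matching code
# paths.

# Minimum Fitch length by exhaustive enumeration of ancestral states.
brute_fitch <- function(phy, states) {
  # states: named integer vector of single states 1..4 per tip (no ambiguity)
  n_tip <- length(phy$tip.label)
  m <- phy$Nnode
  st <- states[phy$tip.label]
  combos <- as.matrix(expand.grid(rep(list(1:4), m)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    assign_all <- c(st, combos[r, ])
    ch <- sum(assign_all[phy$edge[, 1]] != assign_all[phy$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# Minimum linear (Manhattan) continuous length by enumerating internal
# assignments over the set of leaf values (optimal L1 solutions occur at
# data points).
brute_farris <- function(phy, values) {
  vals <- values[phy$tip.label]
  cand <- sort(unique(vals))
  m <- phy$Nnode
  combos <- as.matrix(expand.grid(rep(list(cand), m)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    assign_all <- c(vals, combos[r, ])
    len <- sum(abs(assign_all[phy$edge[, 1]] - assign_all[phy$edge[, 2]]))
    best <- min(best, len)
  }
  best
}

# Independent intersection-over-union split similarity (same definition as
# the package's, implemented separately).
oracle_split_sim <- function(s1, s2, labels) {
  c1 <- setdiff(labels, s1); c2 <- setdiff(labels, s2)
  iou <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  max(min(iou(s1, s2), iou(c1, c2)), min(iou(s1, c2), iou(c1, s2)))
}

# Brute-force maximum-weight injective matching between two split lists.
oracle_best_matching <- function(sides1, sides2, labels) {
  sim <- outer(seq_along(sides1), seq_along(sides2),
               Vectorize(function(i, j)
                 oracle_split_sim(sides1[[i]], sides2[[j]], labels)))
  if (!length(sides1) || !length(sides2)) return(0)
  rec <- function(i, used) {
    if (i > length(sides1)) return(0)
    best <- rec(i + 1L, used)  # leave split i unmatched
    for (j in seq_along(sides2)) if (!used[j]) {
      used2 <- used; used2[j] <- TRUE
      best <- max(best, sim[i, j] + rec(i + 1L, used2))
    }
    best
  }
  rec(1L, rep(FALSE, length(sides2)))
}

# Split sides of a tree via phangorn (independent of the package).
oracle_sides <- function(phy) {
  n <- length(phy$tip.label)
  sp <- phangorn::as.splits(ape::unroot(phy))
  labs <- attr(sp, "labels")
  anchor <- min(labs)
  out <- list()
  for (s in sp) {
    if (length(s) < 2L || n - length(s) < 2L) next
    side <- labs[s]
    if (anchor %in% side) side <- setdiff(labs, side)
    out <- c(out, list(sort(side)))
  }
  unique(out)
}

# Random single-state molecular column as characters.
random_column <- function(labels) {
  stats::setNames(sample(c("A", "C", "G", "T"), length(labels),
                         replace = TRUE), labels)
}

# Tiny clean (homoplasy-free) alignment generated from a known tree: one
# binary character per internal edge, plus invariant padding.
clean_matrix_for <- function(phy, pad = 2L) {
  sides <- oracle_sides(phy)
  labs <- phy$tip.label
  cols <- lapply(sides, function(s) ifelse(labs %in% s, "A", "T"))
  cols <- c(cols, replicate(pad, rep("A", length(labs)), simplify = FALSE))
  m <- do.call(cbind, cols)
  rownames(m) <- labs
  gene_alignment("clean", m)
}
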