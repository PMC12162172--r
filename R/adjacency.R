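# Light-weight unrooted-tree representation used by the tree search.
#
# A "utree" is a list with fields
#   nbr    : list of integer neighbour vectors, indexed by node id
#   n_tip  : number of leaves; leaves are node ids 1..n_tip
#   labels : character vector of leaf labels (id order)
# Internal nodes have ids > n_tip and degree >= 3 (degree-2 nodes only
# transiently during edit operations).  Trees produced by the search are
# strictly binary.

utree_from_phylo <- function(phy) {
  phy <- ape::collapse.singles(phy)
  if (!ape::is.rooted(phy) || phy$Nnode > 1L || length(phy$tip.label) > 2L)
    phy <- if (length(phy$tip.label) >= 3L) ape::unroot(phy) else phy
  n_tip <- length(phy$tip.label)
  n_nodes <- n_tip + phy$Nnode
  nbr <- vector("list", n_nodes)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  list(nbr = nbr, n_tip = n_tip, labels = phy$tip.label)
}

phylo_from_utree <- function(ut) {
  n_tip <- ut$n_tip
  if (n_tip == 2L) {
    return(structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2L),
                          tip.label = ut$labels, Nnode = 1L),
                     class = "phylo", order = "cladewise"))
  }
  # root the traversal at the internal node adjacent to tip 1
  start <- ut$nbr[[1L]][1L]
  n_nodes <- length(ut$nbr)
  new_id <- integer(n_nodes)
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  next_internal <- n_tip + 1L
  parent_edge <- list()
  stack <- list(c(start, 1L))  # (node, parent-in-traversal)
  # preorder renumbering of internal nodes
  order_nodes <- integer(0)
  parents <- integer(n_nodes)
  visited <- logical(n_nodes)
  visited[1L] <- TRUE
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top[1L]; p <- top[2L]
    if (visited[v]) next
    visited[v] <- TRUE
    parents[v] <- p
    if (v > n_tip) {
      new_id[v] <- next_internal
      next_internal <- next_internal + 1L
    }
    order_nodes <- c(order_nodes, v)
    for (w in ut$nbr[[v]]) if (!visited[w]) stack[[length(stack) + 1L]] <- c(w, v)
  }
  edges <- matrix(0L, 0L, 2L)
  rows <- lapply(order_nodes[-1L], function(v) c(new_id[parents[v]], new_id[v]))
  edges <- do.call(rbind, c(list(matrix(c(new_id[start], 1L), 1L)), rows))
  structure(list(edge = edges, tip.label = ut$labels,
                 Nnode = next_internal - 1L - n_tip),
            class = "phylo")
}

# All undirected edges as a 2-column matrix (u < v per row).
utree_edges <- function(ut) {
  out <- matrix(0L, 0L, 2L)
  rows <- list()
  for (v in seq_along(ut$nbr)) for (w in ut$nbr[[v]]) if (v < w)
    rows[[length(rows) + 1L]] <- c(v, w)
  do.call(rbind, rows)
}

# Postorder traversal rooted at a tip: returns nodes in postorder together
# with each node's children under that rooting.  Used by all scoring code.
utree_postorder <- function(ut, root_tip = 1L) {
  n_nodes <- length(ut$nbr)
  parent <- integer(n_nodes)
  visited <- logical(n_nodes)
  visited[root_tip] <- TRUE
  start <- ut$nbr[[root_tip]][1L]
  stack <- c(start)
  parent[start] <- root_tip
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (visited[v]) next
    visited[v] <- TRUE
    pre <- c(pre, v)
    for (w in ut$nbr[[v]]) if (!visited[w]) {
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  post <- rev(pre)
  children <- vector("list", n_nodes)
  for (v in post) children[[parent[v]]] <- c(children[[parent[v]]], v)
  list(post = post, children = children, parent = parent, start = start)
}

# Grow a uniform random labelled binary topology by sequential attachment:
# each new leaf subdivides a uniformly chosen edge of the current tree.
utree_random <- function(labels) {
  n <- length(labels)
  nbr <- vector("list", 2L * n - 2L)
  hub <- n + 1L
  nbr[[1L]] <- hub; nbr[[2L]] <- hub; nbr[[3L]] <- hub
  nbr[[hub]] <- c(1L, 2L, 3L)
  next_internal <- n + 2L
  ut <- list(nbr = nbr, n_tip = n, labels = labels)
  if (n >= 4L) for (tip in 4L:n) {
    edges <- utree_edges(ut)
    e <- edges[sample.int(nrow(edges), 1L), ]
    ut <- utree_attach_tip(ut, tip, e[1L], e[2L], next_internal)
    next_internal <- next_internal + 1L
  }
  ut$nbr <- ut$nbr[seq_len(next_internal - 1L)]
  ut
}

# Subdivide edge (u,v) with new internal node w and hang `tip` from w.
utree_attach_tip <- function(ut, tip, u, v, w) {
  nbr <- ut$nbr
  if (length(nbr) < w) nbr[[w]] <- integer(0)
  nbr[[u]][nbr[[u]] == v] <- w
  nbr[[v]][nbr[[v]] == u] <- w
  nbr[[w]] <- c(u, v, tip)
  nbr[[tip]] <- w
  ut$nbr <- nbr
  ut
}

# Remove a leaf and suppress the resulting degree-2 node.
utree_drop_tip <- function(ut, tip) {
  nbr <- ut$nbr
  w <- nbr[[tip]]
  rest <- setdiff(nbr[[w]], tip)
  stopifnot(length(rest) == 2L)
  nbr[[rest[1L]]][nbr[[rest[1L]]] == w] <- rest[2L]
  nbr[[rest[2L]]][nbr[[rest[2L]]] == w] <- rest[1L]
  nbr[[w]] <- integer(0)
  nbr[[tip]] <- integer(0)
  ut$nbr <- nbr
  ut
}

# Canonical split keys of a utree (non-trivial splits only), as strings of
# sorted tip ids on the side away from tip 1.
utree_split_keys <- function(ut) {
  po <- utree_postorder(ut)
  n_tip <- ut$n_tip
  sets <- vector("list", length(ut$nbr))
  keys <- character(0)
  for (v in po$post) {
    if (v <= n_tip) { sets[[v]] <- v; next }
    s <- sort(unlist(sets[po$children[[v]]], use.names = FALSE))
    sets[[v]] <- s
    if (v != po$start && length(s) >= 2L && n_tip - length(s) >= 2L)
      keys <- c(keys, paste(s, collapse = ","))
  }
  keys
}
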