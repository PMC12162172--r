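# Constrained heuristic maximum-parsimony tree search: random addition
# sequences with TBR branch swapping, strict-consensus reporting and
# bootstrap support.

#' Search configuration for the parsimony tree search
#'
#' Defaults mirror the analysis protocol (100 random addition sequences
#' with TBR branch swapping, retaining up to 100 equally parsimonious
#' trees); scale `n_replicates` down for large matrices or quick runs.
#'
#' @param n_replicates Number of random-addition-sequence replicates.
#' @param hold_per_replicate Maximum number of equally parsimonious trees
#'   retained.
#' @param seed Integer seed driving all randomness of the search.
#' @param constraints Either a named character vector mapping leaf labels
#'   to groups whose monophyly is enforced, a list of explicit clades
#'   (character vectors), or `NULL`.
#' @param continuous_weight Weight of the continuous partition (applied at
#'   encoding time; recorded here for run reports).
#' @return A list of class `search_config`.
#' @export
search_config <- function(n_replicates = 100L, hold_per_replicate = 100L,
                          seed = 0L, constraints = NULL,
                          continuous_weight = 1) {
  stopifnot(n_replicates >= 1L, hold_per_replicate >= 1L)
  structure(list(n_replicates = as.integer(n_replicates),
                 hold_per_replicate = as.integer(hold_per_replicate),
                 seed = as.integer(seed), constraints = constraints,
                 continuous_weight = continuous_weight),
            class = "search_config")
}

# Normalize constraints to a list of label vectors (size >= 2) and check
# feasibility (clades must be pairwise nested or disjoint).
normalize_constraints <- function(constraints, labels) {
  if (is.null(constraints)) return(list())
  if (!is.list(constraints)) {
    grp <- constraints[intersect(names(constraints), labels)]
    sets <- split(names(grp), unname(grp))
  } else sets <- lapply(constraints, intersect, y = labels)
  sets <- Filter(function(s) length(s) >= 2L && length(s) < length(labels),
                 sets)
  if (length(sets) > 1L) {
    for (i in seq_along(sets)[-1]) for (j in seq_len(i - 1L)) {
      a <- sets[[i]]; b <- sets[[j]]
      ov <- length(intersect(a, b))
      if (ov && ov < length(a) && ov < length(b))
        stopf("infeasible constraints: groups overlap without nesting (%s / %s)",
              paste(a, collapse = ","), paste(b, collapse = ","))
    }
  }
  unname(sets)
}

# Does the (possibly partial) utree keep every constraint monophyletic?
# csets: list of integer tip-id vectors; root_tip must be attached.
utree_constraints_ok <- function(ut, csets, root_tip) {
  if (!length(csets)) return(TRUE)
  po <- utree_postorder(ut, root_tip)
  n_nodes <- length(ut$nbr)
  attached <- logical(ut$n_tip)
  for (v in po$post) if (v <= ut$n_tip) attached[v] <- TRUE
  attached[root_tip] <- TRUE
  n_att <- sum(attached)
  G <- length(csets)
  m <- vapply(csets, function(s) sum(attached[s]), 0L)
  active <- which(m >= 2L & m <= n_att - 2L)
  if (!length(active)) return(TRUE)
  in_set <- matrix(FALSE, ut$n_tip, length(active))
  for (j in seq_along(active))
    in_set[csets[[active[j]]], j] <- TRUE
  cnt <- matrix(0L, n_nodes, length(active))
  tot <- integer(n_nodes)
  ok <- logical(length(active))
  for (v in po$post) {
    if (v <= ut$n_tip) {
      cnt[v, ] <- in_set[v, ]
      tot[v] <- 1L
    } else {
      kids <- po$children[[v]]
      cnt[v, ] <- .colSums(cnt[kids, , drop = FALSE], length(kids),
                           length(active))
      tot[v] <- sum(tot[kids])
    }
    ok <- ok | (cnt[v, ] == m[active] & tot[v] == m[active]) |
      (cnt[v, ] == 0L & tot[v] == n_att - m[active])
    if (all(ok)) return(TRUE)
  }
  all(ok)
}

# Random-order stepwise addition under constraints.
stepwise_addition <- function(td, labels, order, csets) {
  n <- length(labels)
  root_tip <- order[1L]
  nbr <- vector("list", 2L * n - 2L)
  hub <- n + 1L
  nbr[[order[1L]]] <- hub; nbr[[order[2L]]] <- hub; nbr[[order[3L]]] <- hub
  nbr[[hub]] <- order[1:3]
  ut <- list(nbr = nbr, n_tip = n, labels = labels)
  next_internal <- n + 2L
  if (n >= 4L) for (i in 4L:n) {
    tip <- order[i]
    edges <- utree_edges(ut)
    best <- NULL; best_s <- Inf
    for (r in seq_len(nrow(edges))) {
      cand <- utree_attach_tip(ut, tip, edges[r, 1L], edges[r, 2L],
                               next_internal)
      if (!utree_constraints_ok(cand, csets, root_tip)) next
      s <- score_utree(cand, td, root_tip)
      if (s < best_s) { best_s <- s; best <- cand }
    }
    if (is.null(best))
      stopf("stepwise addition: no constraint-compatible insertion for taxon %s",
            labels[tip])
    ut <- best
    next_internal <- next_internal + 1L
  }
  ut
}

# All TBR reconnections of `ut` around one edge, evaluated lazily through
# callback `consider(ut2)`.  Binary trees only.
tbr_scan_edge <- function(ut, u, v, consider) {
  base <- ut$nbr
  base[[u]] <- setdiff(base[[u]], v)
  base[[v]] <- setdiff(base[[v]], u)
  prep_side <- function(x) {
    if (x <= ut$n_tip) return(list(tip = x, edges = NULL, cut = NULL))
    ab <- base[[x]]
    list(tip = NULL, junction = x, cut = sort(ab))
  }
  sideA <- prep_side(u); sideB <- prep_side(v)
  nbr0 <- base
  for (side in list(sideA, sideB)) if (is.null(side$tip)) {
    a <- side$cut[1L]; b <- side$cut[2L]; x <- side$junction
    nbr0[[a]][nbr0[[a]] == x] <- b
    nbr0[[b]][nbr0[[b]] == x] <- a
    nbr0[[x]] <- integer(0)
  }
  comp_edges <- function(from) {
    seen <- logical(length(nbr0)); seen[from] <- TRUE
    stack <- from; rows <- list()
    while (length(stack)) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in nbr0[[a]]) {
        if (a < w || !seen[w]) rows[[length(rows) + 1L]] <- sort(c(a, w))
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    unique(rows)
  }
  attachA <- if (is.null(sideA$tip)) comp_edges(sideA$cut[1L]) else list(NULL)
  attachB <- if (is.null(sideB$tip)) comp_edges(sideB$cut[1L]) else list(NULL)
  for (eA in attachA) for (eB in attachB) {
    # skip the reconnection that regenerates the original tree
    sameA <- is.null(eA) || identical(eA, sideA$cut)
    sameB <- is.null(eB) || identical(eB, sideB$cut)
    if (sameA && sameB) next
    nbr2 <- nbr0
    if (is.null(eA)) pA <- sideA$tip
    else {
      pA <- sideA$junction
      nbr2[[eA[1L]]][nbr2[[eA[1L]]] == eA[2L]] <- pA
      nbr2[[eA[2L]]][nbr2[[eA[2L]]] == eA[1L]] <- pA
      nbr2[[pA]] <- eA
    }
    if (is.null(eB)) pB <- sideB$tip
    else {
      pB <- sideB$junction
      nbr2[[eB[1L]]][nbr2[[eB[1L]]] == eB[2L]] <- pB
      nbr2[[eB[2L]]][nbr2[[eB[2L]]] == eB[1L]] <- pB
      nbr2[[pB]] <- eB
    }
    nbr2[[pA]] <- c(nbr2[[pA]], pB)
    nbr2[[pB]] <- c(nbr2[[pB]], pA)
    ut2 <- ut
    ut2$nbr <- nbr2
    if (!is.null(consider(ut2))) return(invisible(TRUE))
  }
  invisible(FALSE)
}

utree_signature <- function(ut) paste(utree_split_keys(ut), collapse = ";")

# TBR hill-climb from `ut`, first-improvement with restart; collects
# equally parsimonious trees up to `hold`.
tbr_search <- function(ut, td, csets, hold) {
  best_s <- score_utree(ut, td)
  pool <- list(ut)
  sigs <- utree_signature(ut)
  repeat {
    improved <- FALSE
    edges <- utree_edges(ut)
    for (r in seq_len(nrow(edges))) {
      found <- tbr_scan_edge(ut, edges[r, 1L], edges[r, 2L], function(cand) {
        s <- score_utree(cand, td)
        if (s < best_s - 1e-9) {
          if (!utree_constraints_ok(cand, csets, 1L)) return(NULL)
          best_s <<- s
          ut <<- cand
          pool <<- list(cand)
          sigs <<- utree_signature(cand)
          return(TRUE)  # stop scanning; restart sweep
        }
        if (s < best_s + 1e-9 && length(pool) < hold) {
          if (!utree_constraints_ok(cand, csets, 1L)) return(NULL)
          sg <- utree_signature(cand)
          if (!sg %in% sigs) {
            pool[[length(pool) + 1L]] <<- cand
            sigs <<- c(sigs, sg)
          }
        }
        NULL
      })
      if (found) { improved <- TRUE; break }
    }
    if (!improved) break
  }
  list(score = best_s, trees = pool, signatures = sigs)
}

#' Heuristic maximum-parsimony tree search
#'
#' Per replicate, a tree is grown by random-order stepwise addition
#' (inserting each taxon at the score-minimizing edge) and refined by TBR
#' branch swapping to a local optimum, accepting strictly better trees and
#' retaining equally parsimonious ones up to the hold limit.  Replicates
#' are pooled; all trees attaining the pooled best score are returned.
#' Every returned tree satisfies the monophyly constraints.
#'
#' @param matrix An `encoded_matrix` (see [encode_supermatrix()]).
#' @param config A [search_config()].
#' @return List with `trees` (list of `phylo`), `score`, `n_trees`,
#'   `config`.
#' @export
parsimony_search <- function(matrix, config = search_config()) {
  stopifnot(inherits(matrix, "encoded_matrix"))
  labels <- matrix$taxa
  if (length(labels) < 4L) stopf("parsimony_search: need at least 4 taxa")
  csets_lab <- normalize_constraints(config$constraints, labels)
  csets <- lapply(csets_lab, function(s) match(s, labels))
  td <- encoded_for_labels(matrix, labels)
  rep_seeds <- derive_seeds(config$seed, config$n_replicates)
  best_s <- Inf
  pool <- list()
  sigs <- character(0)
  for (k in seq_len(config$n_replicates)) {
    order <- with_seed(rep_seeds[k], sample.int(length(labels)))
    ut0 <- stepwise_addition(td, labels, order, csets)
    res <- tbr_search(ut0, td, csets, config$hold_per_replicate)
    if (res$score < best_s - 1e-9) {
      best_s <- res$score
      pool <- res$trees
      sigs <- res$signatures
    } else if (res$score < best_s + 1e-9) {
      for (i in seq_along(res$trees)) {
        if (length(pool) >= config$hold_per_replicate) break
        if (!res$signatures[i] %in% sigs) {
          pool[[length(pool) + 1L]] <- res$trees[[i]]
          sigs <- c(sigs, res$signatures[i])
        }
      }
    }
  }
  trees <- lapply(pool, phylo_from_utree)
  list(trees = trees, score = best_s, n_trees = length(trees),
       config = config)
}

#' Full parsimony analysis: search plus strict consensus
#'
#' @inheritParams parsimony_search
#' @return List with `consensus` (`phylo`), `best_score`, `n_best`,
#'   `trees`.
#' @export
parsimony_analysis <- function(matrix, config = search_config()) {
  res <- parsimony_search(matrix, config)
  cons <- strict_consensus(res$trees)
  list(consensus = cons, best_score = res$score, n_best = res$n_trees,
       trees = res$trees)
}

#' Bootstrap support for bipartitions
#'
#' Columns are resampled with replacement within each partition
#' (preserving partition sizes), the search is re-run with a reduced
#' replicate count, and bipartition frequencies of the per-repetition
#' strict consensus trees are tabulated.
#'
#' @param sm A `supermatrix`.
#' @param config A [search_config()].
#' @param n_bootstrap Number of bootstrap repetitions (default 100).
#' @param reduced_replicates Addition-sequence replicates per repetition
#'   (default 10).
#' @param resample_continuous Resample the continuous partition too?
#'   Default `TRUE` (all partitions are resampled).
#' @param continuous_weight,rescale,gap_as_state Passed to
#'   [encode_supermatrix()].
#' @return Data frame with columns `bipartition` (sorted side away from
#'   the alphabetically first taxon, comma-separated) and `support`
#'   (percentage in `[0, 100]`).
#' @export
bootstrap_support <- function(sm, config = search_config(),
                              n_bootstrap = 100L, reduced_replicates = 10L,
                              resample_continuous = TRUE,
                              continuous_weight = 1, rescale = TRUE,
                              gap_as_state = FALSE) {
  stopifnot(inherits(sm, "supermatrix"))
  boot_seeds <- derive_seeds(config$seed, n_bootstrap)
  tab <- new.env(parent = emptyenv())
  anchor <- min(sm$taxa)
  mol_parts <- sm$partitions[sm$partitions$type == "molecular", , drop = FALSE]
  for (b in seq_len(n_bootstrap)) {
    sm_b <- sm
    part_seeds <- derive_seeds(boot_seeds[b], nrow(mol_parts) + 1L)
    if (!is.null(sm$mol) && ncol(sm$mol)) {
      idx <- integer(0)
      for (p in seq_len(nrow(mol_parts))) {
        cols <- (mol_parts$start[p] + 1L):mol_parts$end[p]
        idx <- c(idx, with_seed(part_seeds[p],
                                cols[sample.int(length(cols), replace = TRUE)]))
      }
      sm_b$mol <- sm$mol[, idx, drop = FALSE]
    }
    if (!is.null(sm$cont) && resample_continuous) {
      jdx <- with_seed(part_seeds[length(part_seeds)],
                       sample.int(ncol(sm$cont), replace = TRUE))
      sm_b$cont <- sm$cont[, jdx, drop = FALSE]
    }
    enc_b <- encode_supermatrix(sm_b, continuous_weight = continuous_weight,
                                rescale = rescale, gap_as_state = gap_as_state)
    cfg_b <- config
    cfg_b$n_replicates <- as.integer(reduced_replicates)
    cfg_b$seed <- boot_seeds[b]
    cons <- parsimony_analysis(enc_b, cfg_b)$consensus
    for (s in split_sides(cons)) {
      key <- paste(s, collapse = ",")
      tab[[key]] <- (tab[[key]] %||% 0) + 1
    }
  }
  keys <- ls(tab)
  data.frame(bipartition = keys,
             support = vapply(keys, function(k) 100 * tab[[k]] / n_bootstrap, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
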