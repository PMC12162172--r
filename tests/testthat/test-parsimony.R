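test_that("Fitch lengths match the exhaustive ancestral-state oracle", {
  tr <- parse_newick("((A1,A2),(C1,C2));")
  expect_equal(fitch_length(tr, c(A1 = "A", A2 = "A", C1 = "C", C2 = "C")), 1L)
  expect_equal(fitch_length(tr, c(A1 = "A", A2 = "A", C1 = "A", C2 = "A")), 0L)
  # missing data is full ambiguity, never an error
  expect_equal(fitch_length(tr, c(A1 = "A", A2 = "?", C1 = "C", C2 = "-")), 1L)

  labs <- sprintf("t%d", 1:6)
  base_int <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (seed in 1:25) {
    set.seed(seed)
    tr6 <- random_binary_tree(labs, seed = seed)
    col <- random_column(labs)
    got <- fitch_length(tr6, col)
    exp <- brute_fitch(ape::unroot(tr6), stats::setNames(base_int[col],
                                                         names(col)))
    expect_equal(got, exp, info = sprintf("seed %d", seed))
  }
})

test_that("Farris continuous lengths match the brute-force oracle", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(farris_continuous_length(tr, c(A = 5, B = 5, C = 5, D = 5)), 0)
  expect_equal(farris_continuous_length(tr, c(A = 0, B = 0, C = 1, D = 1)), 1)
  expect_equal(farris_continuous_length(tr, c(A = 0, B = 1, C = 0, D = 1)), 2)
  expect_equal(farris_continuous_length(tr, c(A = 0, B = NA, C = 1, D = 1)), 1)

  labs <- sprintf("t%d", 1:6)
  for (seed in 1:25) {
    set.seed(1000 + seed)
    tr6 <- random_binary_tree(labs, seed = seed)
    vals <- stats::setNames(round(stats::rnorm(6), 2), labs)
    got <- farris_continuous_length(tr6, vals)
    exp <- brute_farris(ape::unroot(tr6), vals)
    expect_equal(got, exp, tolerance = 1e-9, info = sprintf("seed %d", seed))
  }
})

test_that("tree scores compose Fitch and weighted Farris components", {
  labs <- c("A", "B", "C", "D", "E")
  tr <- random_binary_tree(labs, seed = 3)
  g <- gene_alignment("g1", stats::setNames(
    c("ACGT", "ACGA", "TCGA", "TCTT", "GCTT"), labs))
  traits <- trait_matrix(matrix(c(0, 1, 2, 3, 4, 1, 1, 0, 0, 1), 5,
                                dimnames = list(labs, NULL)))
  sm <- concatenate(list(g), traits = traits)
  enc <- encode_supermatrix(sm, continuous_weight = 2, rescale = FALSE)
  by_hand <- sum(vapply(1:4, function(j)
    fitch_length(tr, stats::setNames(g$seq[, j], labs)), 0L)) +
    2 * sum(vapply(1:2, function(j)
      farris_continuous_length(tr, traits[, j]), 0))
  expect_equal(tree_score(tr, enc), by_hand, tolerance = 1e-9)

  # molecular-only: continuous weight irrelevant
  enc0 <- encode_supermatrix(concatenate(list(g)), continuous_weight = 99)
  expect_equal(tree_score(tr, enc0),
               sum(vapply(1:4, function(j)
                 fitch_length(tr, stats::setNames(g$seq[, j], labs)), 0L)))
  expect_error(tree_score(parse_newick("((A,B),(C,X));"), enc0), "differ")
})

test_that("scores are invariant to rooting and scale equivariant", {
  labs <- sprintf("t%d", 1:7)
  tr <- random_binary_tree(labs, seed = 5)
  g <- gene_alignment("g", stats::setNames(vapply(1:7, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""), ""), labs))
  set.seed(9)
  traits <- trait_matrix(matrix(stats::rnorm(21), 7,
                                dimnames = list(labs, NULL)))
  enc <- encode_supermatrix(concatenate(list(g), traits = traits),
                            rescale = FALSE)
  s0 <- tree_score(tr, enc)
  for (node in c("t2", "t5", "t7")) {
    rooted <- ape::root(tr, outgroup = node, resolve.root = TRUE)
    expect_equal(tree_score(rooted, enc), s0, tolerance = 1e-9)
  }
  # multiplying one trait by c multiplies its length by |c| (no rescaling)
  t2 <- traits; t2[, 1] <- -3.5 * t2[, 1]
  l1 <- farris_continuous_length(tr, traits[, 1])
  expect_equal(farris_continuous_length(tr, t2[, 1]), 3.5 * l1,
               tolerance = 1e-9)
})

test_that("adding or duplicating columns changes scores monotonically", {
  labs <- sprintf("t%d", 1:6)
  tr <- random_binary_tree(labs, seed = 8)
  seqs <- stats::setNames(vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""), ""), labs)
  g <- gene_alignment("g", seqs)
  base <- tree_score(tr, encode_supermatrix(concatenate(list(g))))
  wider <- gene_alignment("g", stats::setNames(paste0(seqs, "ACCGTA"), labs))
  expect_gte(tree_score(tr, encode_supermatrix(concatenate(list(wider)))), base)
  doubled <- gene_alignment("g", stats::setNames(paste0(seqs, seqs), labs))
  expect_equal(tree_score(tr, encode_supermatrix(concatenate(list(doubled)))),
               2 * base)
})

test_that("heuristic search attains the exhaustive optimum on small data", {
  skip_if_not_installed("phangorn")
  # n = 6: all 105 topologies; n = 7: all 945
  for (n in c(6L, 7L)) {
    labs <- sprintf("t%d", seq_len(n))
    set.seed(n)
    seqs <- stats::setNames(vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), ""), labs)
    traits <- trait_matrix(matrix(stats::rnorm(3 * n), n,
                                  dimnames = list(labs, NULL)))
    enc <- encode_supermatrix(concatenate(list(gene_alignment("g", seqs)),
                                          traits = traits))
    all_tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
    expect_length(all_tops, if (n == 6L) 105L else 945L)
    exhaustive <- min(vapply(all_tops, tree_score, 0, matrix = enc))
    res <- parsimony_search(enc, search_config(n_replicates = 5, seed = 1))
    expect_equal(res$score, exhaustive, tolerance = 1e-9)
  }
})

test_that("search on clean congruent data recovers the generating tree", {
  labs <- sprintf("t%d", 1:6)
  gen <- random_binary_tree(labs, seed = 21)
  g <- clean_matrix_for(gen)
  enc <- encode_supermatrix(concatenate(list(g)))
  res <- parsimony_search(enc, search_config(n_replicates = 5, seed = 2))
  expect_equal(res$n_trees, 1L)
  expect_setequal(totem:::split_keys(res$trees[[1]]), totem:::split_keys(gen))
  expect_equal(res$score, length(totem:::split_sides(gen)))
})

test_that("constraints are honoured even against the data's preference", {
  labs <- c("A1", "A2", "B1", "B2", "C1", "C2")
  # data favour pairing A1 with B1 etc.; constraint forces {A1,A2} together
  seqs <- stats::setNames(c("AAAA", "TTTT", "AAAT", "TTTA", "AATT", "TTAA"),
                          labs)
  enc <- encode_supermatrix(concatenate(list(gene_alignment("g", seqs))))
  cons <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", C1 = "C", C2 = "C")
  res <- parsimony_search(enc, search_config(n_replicates = 4, seed = 3,
                                             constraints = cons))
  for (tr in res$trees) {
    mono <- check_monophyly(tr, cons)
    expect_true(all(mono))
  }
  free <- parsimony_search(enc, search_config(n_replicates = 4, seed = 3))
  expect_lt(free$score, res$score)  # the constraint must cost something here
  expect_error(parsimony_search(enc, search_config(
    constraints = list(c("A1", "A2", "B1"), c("B1", "B2")))),
    "infeasible")
})

test_that("equally parsimonious resolutions collapse in the consensus", {
  labs <- c("A", "B", "C", "D")
  # two columns supporting conflicting splits -> tie between topologies
  g <- gene_alignment("g", stats::setNames(c("AA", "AC", "CA", "CC"), labs))
  enc <- encode_supermatrix(concatenate(list(g)))
  ana <- parsimony_analysis(enc, search_config(n_replicates = 4, seed = 1))
  expect_gte(ana$n_best, 2L)
  expect_length(bipartitions(ana$consensus), 0L)
  # determinism under a fixed seed
  ana2 <- parsimony_analysis(enc, search_config(n_replicates = 4, seed = 1))
  expect_equal(ana$best_score, ana2$best_score)
  expect_equal(lapply(ana$trees, totem:::split_keys),
               lapply(ana2$trees, totem:::split_keys))
})

test_that("bootstrap support is high for well-supported clades and stable", {
  labs <- sprintf("t%d", 1:6)
  gen <- random_binary_tree(labs, seed = 30)
  # long invariant-free clean alignment: every split supported by many cols
  sides <- totem:::split_sides(gen)
  cols <- do.call(cbind, rep(lapply(sides, function(s)
    ifelse(labs %in% s, "A", "T")), 40))
  rownames(cols) <- labs
  sm <- concatenate(list(gene_alignment("g", cols)))
  bs <- bootstrap_support(sm, search_config(seed = 5), n_bootstrap = 20,
                          reduced_replicates = 2)
  true_keys <- vapply(sides, paste, "", collapse = ",")
  sup <- bs$support[match(true_keys, bs$bipartition)]
  expect_true(all(sup >= 95))
  bs2 <- bootstrap_support(sm, search_config(seed = 5), n_bootstrap = 20,
                           reduced_replicates = 2)
  expect_equal(bs, bs2)
})
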