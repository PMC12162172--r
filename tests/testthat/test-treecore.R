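test_that("newick parsing validates input and round-trips bipartitions", {
  tr <- parse_newick("(A,B,(C,D));")
  expect_setequal(leaf_labels(tr), c("A", "B", "C", "D"))
  bp <- bipartitions(tr)
  expect_length(bp, 1L)
  expect_equal(bp[[1]]$side_a, c("A", "B"))
  expect_equal(bp[[1]]$side_b, c("C", "D"))

  expect_error(parse_newick("((A,B,(C);"), "unclosed")
  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick("(A,B,(A,C));"), "duplicate")

  for (seed in 1:5) {
    t0 <- random_binary_tree(sprintf("t%02d", 1:9), seed = seed)
    rt <- parse_newick(write_newick(t0))
    expect_setequal(totem:::split_keys(rt), totem:::split_keys(t0))
  }
})

test_that("bipartition counts follow n - 3 and polytomies are respected", {
  expect_length(bipartitions(parse_newick("(A,B,C,D);")), 0L)
  expect_length(bipartitions(parse_newick("((((A,B),C),D),E);")), 2L)
  t8 <- random_binary_tree(LETTERS[1:8], seed = 11)
  b8 <- bipartitions(t8)
  expect_length(b8, 5L)
  keys <- vapply(b8, function(b) paste(b$side_b, collapse = ","), "")
  expect_length(unique(keys), 5L)
  for (n in c(4:12, 20, 35, 50)) {
    tr <- random_binary_tree(sprintf("x%02d", 1:n), seed = n)
    expect_length(bipartitions(tr), n - 3L)
  }
})

test_that("random binary trees are uniform over the 3 quartet topologies", {
  partner_of_A <- vapply(1:3000, function(s) {
    tr <- random_binary_tree(c("A", "B", "C", "D"), seed = s)
    side <- totem:::split_sides(tr)[[1]]  # side away from A
    setdiff(c("B", "C", "D"), side)
  }, "")
  freq <- table(partner_of_A) / 3000
  expect_setequal(names(freq), c("B", "C", "D"))
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
  expect_equal(write_newick(random_binary_tree(LETTERS[1:10], seed = 4)),
               write_newick(random_binary_tree(LETTERS[1:10], seed = 4)))
  expect_error(random_binary_tree(c("A", "A", "B"), seed = 1), "duplicate")
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  cons <- strict_consensus(list(t1, t2))
  expect_length(bipartitions(cons), 0L)

  same <- parse_newick("((A,B),((C,D),E));")
  expect_setequal(totem:::split_keys(strict_consensus(list(same, same, same))),
                  totem:::split_keys(same))

  # two 6-leaf trees sharing only {A,B} | rest
  u1 <- parse_newick("((A,B),((C,D),(E,F)));")
  u2 <- parse_newick("((A,B),((C,E),(D,F)));")
  cons2 <- strict_consensus(list(u1, u2))
  k <- totem:::split_keys(cons2)
  expect_length(k, 1L)
  expect_equal(totem:::split_sides(cons2)[[1]], c("C", "D", "E", "F"))

  expect_error(strict_consensus(list(t1, parse_newick("((A,B),(C,E));"))),
               "symmetric difference")

  # property: consensus split set equals the intersection of inputs' splits
  labs <- sprintf("s%02d", 1:8)
  for (seed in 1:6) {
    trees <- lapply(seed * 10 + 1:3, random_binary_tree, leaf_labels = labs)
    cons <- strict_consensus(trees)
    inter <- Reduce(intersect, lapply(trees, totem:::split_keys))
    expect_setequal(totem:::split_keys(cons), inter)
    # cross-check against ape's strict consensus
    ac <- ape::consensus(trees, p = 1, rooted = FALSE)
    expect_setequal(totem:::split_keys(cons), totem:::split_keys(ac))
  }
})

test_that("pruning restricts the topology and commutes with bipartitions", {
  tr <- parse_newick("((A,B),(C,D),(E,F));")
  p <- prune_to(tr, c("A", "C", "E", "F"))
  expect_setequal(totem:::split_keys(p),
                  totem:::split_keys(parse_newick("(A,C,(E,F));")))
  full <- random_binary_tree(LETTERS[1:7], seed = 2)
  expect_setequal(totem:::split_keys(prune_to(full, LETTERS[1:7])),
                  totem:::split_keys(full))
  expect_error(prune_to(tr, c("A", "Z", "B")), "not in tree")
  expect_error(prune_to(tr, c("A", "B")), "at least 3")

  # bipartitions(prune(T,S)) equal the non-trivial restrictions of
  # bipartitions(T) to S, across random 6-leaf trees and subsets
  labs <- LETTERS[1:6]
  for (seed in 1:8) {
    tr6 <- random_binary_tree(labs, seed = seed)
    set.seed(100 + seed)
    keep <- sort(sample(labs, 5))
    pr <- prune_to(tr6, keep)
    restr <- lapply(totem:::split_sides(tr6), intersect, y = keep)
    restr <- Filter(function(s)
      length(s) >= 2 && length(keep) - length(s) >= 2, restr)
    anchor <- min(keep)
    restr <- unique(lapply(restr, function(s)
      if (anchor %in% s) sort(setdiff(keep, s)) else sort(s)))
    expect_setequal(vapply(totem:::split_sides(pr), paste, "", collapse = ","),
                    vapply(restr, paste, "", collapse = ","))
  }
})

test_that("monophyly checks match brute-force edge enumeration", {
  g <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  expect_true(all(check_monophyly(parse_newick("((A1,A2),(B1,B2));"), g)))
  expect_false(any(check_monophyly(parse_newick("((A1,B1),(A2,B2));"), g)))
  expect_error(check_monophyly(parse_newick("((A1,A2),(B1,X));"), g),
               "unassigned")

  # brute force: a group is monophyletic iff one edge separates exactly it
  labs <- c("A1", "A2", "A3", "B1", "B2", "C1", "C2", "C3")
  groups <- substring(labs, 1, 1)
  names(groups) <- labs
  for (seed in 1:10) {
    tr <- random_binary_tree(labs, seed = seed)
    got <- check_monophyly(tr, groups)
    sides <- totem:::split_sides(tr)
    for (gr in unique(groups)) {
      members <- sort(labs[groups == gr])
      hit <- any(vapply(sides, function(s)
        identical(sort(s), members) ||
          identical(sort(setdiff(labs, s)), members), TRUE))
      expected <- hit || length(members) <= 1
      expect_identical(unname(got[gr]), expected)
    }
  }
})

test_that("collapsing monophyletic groups gives the induced genus tree", {
  tr <- parse_newick("((A1,A2),(B1,(C1,C2)));")
  g <- c(A1 = "A", A2 = "A", B1 = "B", C1 = "C", C2 = "C")
  col <- collapse_groups(tr, g)
  expect_setequal(leaf_labels(col), c("A", "B", "C"))
  expect_setequal(totem:::split_keys(col),
                  totem:::split_keys(parse_newick("(A,(B,C));")))
  # all-singleton groups: relabeling only
  tr2 <- parse_newick("((A,B),(C,D));")
  g2 <- c(A = "gA", B = "gB", C = "gC", D = "gD")
  expect_setequal(totem:::split_sides(collapse_groups(tr2, g2))[[1]],
                  c("gC", "gD"))
  expect_error(collapse_groups(parse_newick("((A1,B1),(A2,B2));"),
                               c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")),
               "not monophyletic: A")
})
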