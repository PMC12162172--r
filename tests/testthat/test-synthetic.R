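test_that("reference trees are reproducible unit-height Yule trees", {
  tr <- simulate_reference_tree(40, seed = 1)
  expect_length(bipartitions(tr), 37L)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-12)
  tr2 <- simulate_reference_tree(40, seed = 1)
  expect_equal(write_newick(tr), write_newick(tr2))
  expect_error(simulate_reference_tree(3, seed = 1), "n >= 4")

  # cherry count matches the Yule expectation n/3
  n <- 15
  cherries <- vapply(1:1000, function(s) {
    phy <- simulate_reference_tree(n, seed = s)
    kids <- split(phy$edge[, 2], phy$edge[, 1])
    sum(vapply(kids, function(k) all(k <= n), TRUE))
  }, 0)
  se <- stats::sd(cherries) / sqrt(length(cherries))
  expect_lt(abs(mean(cherries) - n / 3), 3 * se)
})

test_that("Brownian traits have the covariance structure of the tree", {
  # fixed 4-leaf tree with known path lengths
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.8,(C:0.7,D:0.7):0.3);")
  m <- simulate_bm_traits(tr, n_traits = 2000, sigma2 = 1, tau = 0, seed = 5)
  cv <- stats::cov(t(m))
  # shared root-to-MRCA path: 0.8 for (A,B), 0.3 for (C,D), 0 across
  se <- 3 / sqrt(2000)  # generous 3-standard-error band
  expect_lt(abs(cv["A", "B"] - 0.8), se)
  expect_lt(abs(cv["C", "D"] - 0.3), se)
  expect_lt(abs(cv["A", "C"] - 0), se)
  expect_lt(abs(cv["A", "A"] - 1.0), se)

  # sigma2 = 0: i.i.d. noise, off-diagonal covariance ~ 0
  m0 <- simulate_bm_traits(tr, n_traits = 2000, sigma2 = 0, tau = 1, seed = 6)
  cv0 <- stats::cov(t(m0))
  expect_lt(abs(cv0["A", "B"]), se)
  expect_lt(abs(cv0["A", "D"]), se)

  expect_equal(simulate_bm_traits(tr, 10, 1, 0.5, seed = 9),
               simulate_bm_traits(tr, 10, 1, 0.5, seed = 9))
})

test_that("specimen averaging shrinks noise like 1/sqrt(k)", {
  tr <- simulate_reference_tree(12, seed = 3)
  gm <- simulate_bm_traits(tr, n_traits = 400, sigma2 = 1, tau = 0, seed = 4)

  exact <- simulate_specimens_and_average(gm, 4, 0, seed = 1)
  expect_equal(unclass(exact$averaged), unclass(gm), tolerance = 1e-12)
  single <- simulate_specimens_and_average(gm, 1, 0.5, seed = 2)
  expect_equal(unclass(single$averaged), unclass(single$specimens),
               tolerance = 1e-12, ignore_attr = TRUE)

  for (k in c(4, 16)) {
    avg <- simulate_specimens_and_average(gm, k, 1, seed = 7)$averaged
    dev <- avg - gm
    expect_lt(abs(stats::sd(dev) - 1 / sqrt(k)), 3 * stats::sd(dev) /
                sqrt(length(dev)))
  }
})

test_that("Jukes-Cantor alignments follow the expected distance curve", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.4,(C:0.45,D:0.45):0.05);")
  frozen <- simulate_gene_alignment(tr, 200, rate = 0, seed = 1)
  expect_true(all(frozen$seq == frozen$seq[rep(1, 4), ]))

  L <- 5000
  aln <- simulate_gene_alignment(tr, L, rate = 1, seed = 2)
  pdist <- function(a, b) mean(aln$seq[a, ] != aln$seq[b, ])
  expected <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  for (pair in list(c("A", "B", 0.2), c("C", "D", 0.9), c("A", "C", 1.0))) {
    p <- expected(as.numeric(pair[3]))
    se <- sqrt(p * (1 - p) / L)
    expect_lt(abs(pdist(pair[1], pair[2]) - p), 3 * se,
              label = sprintf("pair %s-%s", pair[1], pair[2]))
  }
  expect_equal(simulate_gene_alignment(tr, 50, 0.5, seed = 3)$seq,
               simulate_gene_alignment(tr, 50, 0.5, seed = 3)$seq)
})

test_that("missingness masks preserve coverage and exact counts", {
  tr <- simulate_reference_tree(40, seed = 8)
  genes <- lapply(1:3, function(i)
    simulate_gene_alignment(tr, 30, 0.5, seed = i, gene_name = paste0("g", i)))
  unchanged <- apply_missingness(genes, 0, seed = 1)
  expect_equal(lapply(unchanged, `[[`, "taxa"), lapply(genes, `[[`, "taxa"))

  masked <- apply_missingness(genes, c(0.5, 0.2, 0), seed = 2)
  expect_length(masked[[1]]$taxa, 20L)
  expect_length(masked[[2]]$taxa, 32L)
  expect_length(masked[[3]]$taxa, 40L)
  expect_setequal(unique(unlist(lapply(masked, `[[`, "taxa"))),
                  tr$tip.label)
  expect_error(apply_missingness(genes, 1.2, seed = 1), "fractions")
})

test_that("the full dataset generator is deterministic and round-trips", {
  cfg <- simulation_config(n_genera = 8, n_traits = 6, seed = 5,
                           genes = data.frame(name = c("gA", "gB"),
                                              length = c(40L, 30L),
                                              rate = c(0.4, 0.6)),
                           missing_fraction = 0.25)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_equal(write_newick(ds1$reference), write_newick(ds2$reference))
  expect_equal(ds1$traits, ds2$traits)
  expect_equal(lapply(ds1$genes, `[[`, "seq"), lapply(ds2$genes, `[[`, "seq"))

  dir <- file.path(tempdir(), "totem-ds")
  write_dataset(ds1, dir)
  expect_setequal(leaf_labels(parse_newick(
    paste(readLines(file.path(dir, "reference.nwk")), collapse = ""))),
    ds1$reference$tip.label)
  back <- read_trait_csv(file.path(dir, "traits.csv"))
  expect_equal(unclass(back), unclass(ds1$traits), tolerance = 1e-12)
  g1 <- read_fasta_alignment(file.path(dir, "gA.fasta"), "gA")
  expect_equal(g1$seq, ds1$genes[[1]]$seq)
})
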