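# Synthetic-data generator: reference trees, Brownian-motion continuous
# traits with tunable phylogenetic signal, per-specimen replicates with
# genus averaging, and Jukes-Cantor gene alignments with per-gene
# missing-taxon masks.

#' Simulation configuration
#'
#' Bundles the generator parameters.  `bm_rate` (sigma^2) is the Brownian
#' variance accumulated per unit branch length on a unit-height tree;
#' `noise_sd` (tau) is the standard deviation of independent
#' non-phylogenetic noise added to each leaf value, so `noise_sd = 0`
#' gives pure signal and `bm_rate = 0` pure noise.
#'
#' @param n_genera Number of genera (leaves of the reference tree).
#' @param n_traits Number of continuous traits (default 128, the latent
#'   dimensionality of the image-derived trait vectors being emulated).
#' @param bm_rate Brownian-motion rate sigma^2 per unit branch length.
#' @param noise_sd Non-phylogenetic noise s.d. tau.
#' @param specimens_per_genus Specimen replicates averaged per genus.
#' @param within_genus_sd Specimen-level s.d. around the genus mean.
#' @param genes Data frame with columns `name`, `length`, `rate` (expected
#'   substitutions per site per unit branch length).
#' @param missing_fraction Per-gene fraction of taxa removed (recycled).
#' @param seed Integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genera = 20L, n_traits = 128L, bm_rate = 1,
                              noise_sd = 0, specimens_per_genus = 5L,
                              within_genus_sd = 0.25,
                              genes = data.frame(
                                name = c("g28S", "argK", "cadA", "cadC",
                                         "COI", "topo", "Wg"),
                                length = c(800L, 700L, 600L, 500L, 650L,
                                           700L, 450L),
                                rate = c(0.3, 0.4, 0.4, 0.4, 0.8, 0.4, 0.5)),
                              missing_fraction = 0.2, seed = 0L) {
  stopifnot(n_genera >= 4L, n_traits >= 1L, bm_rate >= 0, noise_sd >= 0,
            specimens_per_genus >= 1L, within_genus_sd >= 0,
            all(missing_fraction >= 0), all(missing_fraction < 1))
  structure(list(n_genera = as.integer(n_genera),
                 n_traits = as.integer(n_traits),
                 bm_rate = bm_rate, noise_sd = noise_sd,
                 specimens_per_genus = as.integer(specimens_per_genus),
                 within_genus_sd = within_genus_sd, genes = genes,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a reference phylogeny
#'
#' A Yule (pure-birth) binary tree, scaled to unit height.  Branch lengths
#' are retained for trait and sequence simulation; strip them (or use
#' [parse_newick()] on the written newick) for topological use.
#'
#' @param n_genera Number of leaves (>= 4).
#' @param seed Integer seed.
#' @param labels Optional leaf labels (default `G01`, `G02`, ...).
#' @return A `phylo` object with branch lengths.
#' @export
simulate_reference_tree <- function(n_genera, seed = 0L, labels = NULL) {
  if (n_genera < 4L) stopf("simulate_reference_tree: need n >= 4")
  phy <- with_seed(seed, ape::rphylo(n_genera, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth
  phy$tip.label <- labels %||% sprintf("G%02d", seq_len(n_genera))
  phy
}

#' Simulate Brownian-motion traits on a tree
#'
#' Each trait evolves independently from root value 0 with rate
#' `sigma2` per unit branch length; independent `N(0, tau^2)` noise is
#' added to every leaf value.  Traits are mutually independent.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param n_traits Number of traits.
#' @param sigma2 Brownian rate per unit branch length.
#' @param tau Leaf-level noise standard deviation.
#' @param seed Integer seed.
#' @return A `trait_matrix` (leaves x traits).
#' @export
simulate_bm_traits <- function(tree, n_traits = 128L, sigma2 = 1, tau = 0,
                               seed = 0L) {
  if (is.null(tree$edge.length))
    stopf("simulate_bm_traits: tree must have branch lengths")
  stopifnot(sigma2 >= 0, tau >= 0)
  phy <- stats::reorder(tree)  # cladewise: parents precede children
  n_tip <- length(phy$tip.label)
  n_nodes <- n_tip + phy$Nnode
  vals <- with_seed(seed, {
    v <- matrix(0, n_nodes, n_traits)
    for (i in seq_len(nrow(phy$edge))) {
      p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
      v[ch, ] <- v[p, ] + stats::rnorm(n_traits, 0,
                                       sqrt(sigma2 * phy$edge.length[i]))
    }
    tips <- v[seq_len(n_tip), , drop = FALSE]
    if (tau > 0) tips <- tips + matrix(stats::rnorm(n_tip * n_traits, 0, tau),
                                       n_tip, n_traits)
    tips
  })
  trait_matrix(vals, taxa = phy$tip.label)
}

#' Simulate per-genus specimen replicates and their averages
#'
#' Each specimen value is the genus mean plus independent
#' `N(0, within_genus_sd^2)` noise; the averaged matrix is the per-genus
#' arithmetic mean of the specimens (the genus-averaging stage applied to
#' image-derived trait vectors).
#'
#' @param genus_means A `trait_matrix` of genus-level means.
#' @param specimens_per_genus Number of specimens per genus (>= 1).
#' @param within_genus_sd Specimen-level standard deviation.
#' @param seed Integer seed.
#' @return List with `specimens` (trait_matrix with rows
#'   `<genus>_s<k>`) and `averaged` (trait_matrix on the genera).
#' @export
simulate_specimens_and_average <- function(genus_means, specimens_per_genus,
                                           within_genus_sd, seed = 0L) {
  stopifnot(specimens_per_genus >= 1L, within_genus_sd >= 0)
  genera <- rownames(genus_means)
  k <- specimens_per_genus
  spec <- with_seed(seed, {
    m <- genus_means[rep(seq_along(genera), each = k), , drop = FALSE]
    m + matrix(stats::rnorm(length(m), 0, within_genus_sd), nrow(m), ncol(m))
  })
  rownames(spec) <- sprintf("%s_s%d", rep(genera, each = k),
                            rep(seq_len(k), length(genera)))
  avg <- t(vapply(seq_along(genera), function(i) {
    rows <- ((i - 1L) * k + 1L):(i * k)
    colMeans(spec[rows, , drop = FALSE])
  }, numeric(ncol(genus_means))))
  list(specimens = trait_matrix(spec),
       averaged = trait_matrix(avg, taxa = genera,
                               trait_names = colnames(genus_means)))
}

#' Simulate a gene alignment under Jukes-Cantor
#'
#' Sites evolve independently from a uniform random root sequence; on a
#' branch of length `t` the probability that a site differs from its
#' parent is `(3/4)(1 - exp(-4 rate t / 3))`, with the new base uniform
#' over the three alternatives.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param length Alignment length (sites, >= 1).
#' @param rate Expected substitutions per site per unit branch length.
#' @param seed Integer seed.
#' @param gene_name Gene label (default `"gene"`).
#' @return A `gene_alignment`.
#' @export
simulate_gene_alignment <- function(tree, length, rate, seed = 0L,
                                    gene_name = "gene") {
  if (is.null(tree$edge.length))
    stopf("simulate_gene_alignment: tree must have branch lengths")
  stopifnot(length >= 1L, rate >= 0)
  bases <- c("A", "C", "G", "T")
  phy <- stats::reorder(tree)
  n_tip <- base::length(phy$tip.label)
  n_nodes <- n_tip + phy$Nnode
  seqs <- with_seed(seed, {
    s <- matrix(0L, n_nodes, length)
    s[n_tip + 1L, ] <- sample.int(4L, length, replace = TRUE)
    for (i in seq_len(nrow(phy$edge))) {
      p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
      pc <- 0.75 * (1 - exp(-4 * rate * phy$edge.length[i] / 3))
      x <- s[p, ]
      hit <- stats::runif(length) < pc
      if (any(hit)) {
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        x[hit] <- 1L + (x[hit] - 1L + shift) %% 4L
      }
      s[ch, ] <- x
    }
    s[seq_len(n_tip), , drop = FALSE]
  })
  m <- matrix(bases[seqs], n_tip, length, dimnames = list(phy$tip.label, NULL))
  gene_alignment(gene_name, m)
}

#' Remove a random subset of taxa from each gene
#'
#' Emulates incomplete database coverage: for each gene a uniform random
#' subset of taxa (of the given fraction, rounded) is dropped.  The draw
#' is retried (bounded) until every taxon retains at least one gene.
#'
#' @param genes List of `gene_alignment` objects on a common taxon set.
#' @param fractions Per-gene removal fractions in `[0, 1)` (recycled).
#' @param seed Integer seed.
#' @param max_retries Retry bound before erroring (default 100).
#' @return List of `gene_alignment` objects.
#' @export
apply_missingness <- function(genes, fractions, seed = 0L, max_retries = 100L) {
  fractions <- rep_len(fractions, base::length(genes))
  if (any(fractions < 0 | fractions >= 1))
    stopf("apply_missingness: fractions must be in [0, 1)")
  all_taxa <- unique(unlist(lapply(genes, function(g) g$taxa)))
  try_seeds <- derive_seeds(seed, max_retries)
  for (r in seq_len(max_retries)) {
    keep_sets <- with_seed(try_seeds[r], lapply(seq_along(genes), function(i) {
      tx <- genes[[i]]$taxa
      drop_n <- round(fractions[i] * base::length(tx))
      if (drop_n == 0L) return(tx)
      setdiff(tx, tx[sample.int(base::length(tx), drop_n)])
    }))
    if (setequal(unique(unlist(keep_sets)), all_taxa)) {
      return(lapply(seq_along(genes), function(i) {
        g <- genes[[i]]
        gene_alignment(g$gene, g$seq[keep_sets[[i]], , drop = FALSE])
      }))
    }
  }
  stopf("apply_missingness: could not cover every taxon in %d retries",
        max_retries)
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper producing everything the analysis consumes: a
#' unit-height Yule reference tree, genus-level Brownian traits observed
#' through specimen replicates and averaging, and gene alignments with
#' missing-taxon masks.
#'
#' @param config A [simulation_config()].
#' @return List with `reference` (with branch lengths),
#'   `reference_topology` (branch lengths dropped), `genus_means`,
#'   `specimens`, `traits` (averaged), `genes` (after missingness).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  seeds <- derive_seeds(config$seed, 4L + nrow(config$genes))
  tree <- simulate_reference_tree(config$n_genera, seed = seeds[1])
  genus_means <- simulate_bm_traits(tree, config$n_traits,
                                    sigma2 = config$bm_rate,
                                    tau = config$noise_sd, seed = seeds[2])
  sp <- simulate_specimens_and_average(genus_means,
                                       config$specimens_per_genus,
                                       config$within_genus_sd,
                                       seed = seeds[3])
  genes <- lapply(seq_len(nrow(config$genes)), function(i)
    simulate_gene_alignment(tree, config$genes$length[i],
                            config$genes$rate[i], seed = seeds[4L + i],
                            gene_name = config$genes$name[i]))
  genes <- apply_missingness(genes, config$missing_fraction, seed = seeds[4])
  topo <- tree
  topo$edge.length <- NULL
  list(reference = tree, reference_topology = topo,
       genus_means = genus_means, specimens = sp$specimens,
       traits = sp$averaged, genes = genes, config = config)
}

#' Write a synthetic dataset to disk in the formats the readers consume
#'
#' Writes the reference newick (without branch lengths), the averaged
#' trait CSV, one aligned FASTA per gene, and a JSON stamp with the seed
#' and configuration.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(dataset$reference_topology, file.path(dir, "reference.nwk"))
  write_trait_csv(dataset$traits, file.path(dir, "traits.csv"))
  for (g in dataset$genes)
    write_fasta_alignment(g, file.path(dir, sprintf("%s.fasta", g$gene)))
  cfg <- unclass(dataset$config)
  cfg$genes <- as.list(cfg$genes)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
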