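Package: totem
Title: Total-Evidence Parsimony with Continuous Morphological Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for total-evidence phylogenetic inference combining
    continuous morphological trait matrices (e.g. latent features derived
    from specimen images) with aligned molecular gene fragments under
    maximum parsimony.  Implements Fitch scoring for nucleotide characters
    and Farris interval optimization for continuous characters, constrained
    heuristic tree search (random addition sequences with TBR branch
    swapping), strict consensus and bootstrap support, quantitative tree
    comparison against a reference phylogeny (normalized Robinson-Foulds
    and a normalized edge-matching align score), per-trait phylogenetic
    signal quantification with a permutation test, gene-ablation studies,
    and a synthetic-data generator (Yule reference trees, Brownian-motion
    traits with tunable signal, Jukes-Cantor gene alignments with
    missing-taxon masks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
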