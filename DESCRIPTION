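Package: orthodyn
Title: Ancestral Gene-Family Dynamics from Orthogroup Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolutionary dynamics of gene families
    (orthogroups) across a rooted species tree. Implements Dollo parsimony
    for ancestral presence/absence (single gain, unlimited losses),
    unweighted Wagner parsimony for ancestral copy number (linear-cost
    Sankoff dynamic programming), per-node tallies of gains, losses,
    expansions and contractions, species-overlap duplication inference on
    rooted gene trees with a clade-support cutoff, Alien Index screening of
    homology-hit tables for cross-kingdom contamination, and one-sided
    hypergeometric term-enrichment with Benjamini-Hochberg correction and
    term-overlap networks. A synthetic-data generator produces gene-family
    histories, gene trees, hit tables and annotation maps with recorded
    ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
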