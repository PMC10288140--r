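Package: cifevo
Title: Simulating the Molecular Emergence of Cytoplasmic-Incompatibility
    Toxin-Antidote Gene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A codon-based (mu + lambda) evolutionary algorithm that evolves
    in-silico Wolbachia cytoplasmic-incompatibility factor (cif) toxin-antidote
    gene pairs from DNA strings. Fitness of a pair is the sum of five
    components: similarity of the toxin to the cid deubiquitylase and cin
    nuclease consensus schemas, charge-complementary toxin-antidote binding,
    and presence of nuclear-localisation (KRAR) and type-IV-secretion export
    signals, with parsimony pressure on genome length. The package provides
    three population instantiation regimes (random, consensus-seeded, and
    founder mutagenesis), configurable selection, recombination and
    self-adaptive mutation operators, per-generation tracking of fifteen
    observables including where the NLS and T4SS signals evolve (antidote
    versus toxin gene), replicate runners, tidy accessors and trajectory
    plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
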