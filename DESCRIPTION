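Package: seqABC
Title: Invasion-History Inference from Multilocus Sequence Data with
    Coalescent Approximate Bayesian Computation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for reconstructing the invasion history of introduced
    species from aligned mitochondrial and nuclear sequence data.
    Provides descriptive population genetics (haplotype and nucleotide
    diversity, site classification, Tajima's D, Fu and Li's D*, Fu's Fs,
    AMOVA, Mantel tests of isolation by distance), statistical-parsimony
    haplotype networks with outgroup (root) weights, a coalescent
    simulator for declarative divergence/founder-bottleneck scenarios
    with ghost populations and Kimura two-parameter mutation, and an
    Approximate Bayesian Computation engine (reference tables, summary
    statistics, direct-estimate model choice, regression-adjusted
    parameter estimation, and type I/II error evaluation). A synthetic
    data generator reproduces the sampling design of a multi-population
    crayfish survey so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coalsim.R'
    'abc.R'
    'seq_io.R'
    'diversity.R'
    'network.R'
    'structure.R'
    'synthetic_data.R'
    'pipeline.R'
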