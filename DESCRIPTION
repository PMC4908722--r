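Package: phyloMC
Title: Stochastic Temporal Logic Model Checking over Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Treats DNA substitution models and phylogenetic trees as
    continuous-time Markov chains and checks probabilistic temporal-logic
    (CSL-style) properties over them. Provides nucleotide substitution
    models (JC69, K80, F81, GTR) with exact transition probabilities via
    uniformization, a formula language for sequence and topological
    properties (conservation, terminal patterns, point and back mutations),
    exact tree likelihood by Felsenstein pruning with cached partials, a
    linear-time upper-bound heuristic for the likelihood, Yule-process tree
    simulation with sequence evolution, trajectory sampling for Monte-Carlo
    validation, and export of models and likelihood properties to the PRISM
    model-checker dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'phyloMC-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'ctmc.R'
    'mutation-models.R'
    'phylo-tree.R'
    'formula.R'
    'check.R'
    'likelihood.R'
    'simulate.R'
    'prism.R'
    'cli.R'
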