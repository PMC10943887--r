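Package: treefeat
Title: Declarative Feature Networks Solved by Cluster-Tree Elimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Declarative modeling of weighted constraint networks ("feature
    networks": variables over finite integer domains, hard constraints, and
    named groups of real-valued local functions combined by per-feature
    weights), solved exactly by dynamic programming over tree decompositions
    of the dependency graph. A generic cluster-tree elimination engine
    supports both optimization (max-plus algebra) and partition functions
    with exact Boltzmann sampling by stochastic traceback (sum-product
    algebra), with complexity exponential only in the treewidth. Includes
    multidimensional Boltzmann sampling for targeting feature values, and
    ready-made bioinformatics models: multitarget RNA sequence design,
    sequence and pseudoknot sequence-structure alignment with linear or
    affine gap costs, hardwired and softwired parsimony on phylogenetic
    networks, and motif control via deterministic finite automata.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'core_model.R'
    'treedecomp.R'
    'engine.R'
    'solvers.R'
    'app_rna.R'
    'app_align.R'
    'app_phylo.R'
    'fixtures.R'
    'io_cli.R'
    'treefeat-package.R'
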