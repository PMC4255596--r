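Package: dispmut
Title: Disparity Mutagenesis Simulators for Replicore Pedigrees,
    Quasi-Species Error Thresholds and Strand-Asymmetric Genetic
    Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulators and closed-form arithmetic for studying
    lagging-strand-biased (disparity) mutagenesis in semiconservative DNA
    replication. Provides a deterministic replicore pedigree model with
    genotype census, persistence checks and Newick export; an Eigen
    quasi-species mutation-selection engine on Hamming error classes with
    a two-fidelity polymerase mixture and error-threshold location by
    bisection; a genetic algorithm with distinct leading- and
    lagging-strand copy fidelities evaluated on 0/1 knapsack instances
    against an exact dynamic-programming optimum; and genetic-load and
    mutation-budget calculators. A small configuration layer and
    TSV/JSON/Newick writers support reproducible command-line runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
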