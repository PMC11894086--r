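Package: evograph
Title: Moran Evolutionary Dynamics on Graph-Structured Populations
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evolutionary graph theory toolkit for two-type Moran dynamics on
    undirected, unweighted graphs. Implements the four update rules obtained by
    crossing the birth-death event order (Bd, dB) with the choice of individual
    that moves to the vacated node (offspring or parent), including the mutant
    initialisation distribution each rule induces (uniform or temperature
    weighted). Fixation probabilities are computed exactly by absorbing Markov
    chain solvers (full 2^N configuration space for small graphs, a lumped
    centre/leaf-count chain for stars of any size), by closed forms for complete
    and star graphs, and by Monte Carlo simulation. Graphs are classified into
    amplifiers and suppressors of selection or fixation against the complete
    graph reference, including a census over connected Erdos-Renyi samples.
    Long-term origin-fixation (weak mutation) dynamics provide steady-state
    fitness distributions, their moments, and effective population size
    estimates from the power-law exponent of fixation probability ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
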