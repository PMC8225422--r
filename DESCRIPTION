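Package: plastinet
Title: Evolutionary Structural Plasticity and Synchronization in
    Hodgkin-Huxley Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates networks of Hodgkin-Huxley neurons whose functional
    connectivity evolves with the membrane potentials: each neuron carries a
    position vector confined to a periodic spatial domain, overlaps between
    domains define the fixed structural wiring, and a potential-driven
    attraction/repulsion rule moves the positions so that a distance
    threshold makes and breaks functional couplings over time.  Includes the
    per-window synchronization analysis (graph-Laplacian second eigenvalue,
    Sylvester negative-definiteness certificate for exponential
    synchronization), the synchronization index based on the population
    standard deviation of the membrane potentials, and modularity-based
    community detection with co-membership tracking of stable neuron groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
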