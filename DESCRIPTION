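Package: macrocycler
Title: Energy-Based Backbone Sampling and Stability Analysis for Cyclic Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis tools for cyclic peptide macrocycles with
    mixed L/D chirality. Encodes backbone closure as a smooth cyclic error
    function over (phi, psi) torsion space, samples closed low-energy
    backbones with a layered simulated annealing scheme over a symmetrized
    glycine Ramachandran map, clusters candidates by cyclically canonical
    torsion-bin strings, and scores conformational stability with the PNear
    folding-funnel statistic. Includes a genetic-algorithm energy-landscape
    sampler (ClusterGen) with crossover, mutation and greedy energy-based
    RMSD clustering, landscape reshaping, Ramachandran-stability filtering
    for small macrocycles, a structure-prediction protocol, and free-energy
    surface histogramming over RMSD and radius of gyration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    bio3d,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
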