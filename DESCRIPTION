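Package: fraggrow
Title: Fragment Growing and Active-Position Prediction for Fragment-Based Drug Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which hydrogen or fluorine position of an active seed
    fragment should be chemically modified to increase binding affinity.
    Virtual compounds are generated by replacing each replaceable position of
    the seed with small hydrocarbon side chains drawn from three nested
    template sets, screened for intramolecular clashes, energy-minimized with
    a lightweight force field using a distance-dependent dielectric, and
    scored against a rigid receptor pocket on a precomputed three-channel
    grid. Modified positions are ranked by the best docking score of any
    compound grown there. Includes ensemble (multi-structure) score merging,
    a true-lead spiking evaluation, deterministic synthetic receptor/seed
    fixtures, and embedded benchmark records of 15 published
    fragment-evolution case studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
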