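Package: MOFBA
Title: Multi-Objective Flux Balance and Variability Analysis for Microbial
    Communities
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based modeling of microbial ecosystems in which every
    community member keeps its own growth objective. Assembles per-strain
    metabolic models into a compartmentalized community model with a shared
    metabolite pool, computes the exact Pareto front of the per-strain growth
    objectives by outer approximation (multi-objective flux balance analysis),
    explores flux variability around Pareto-optimal states (multi-objective
    flux variability analysis), and ranks community states thermodynamically
    by maximizing the chemical motive force over exchange-flux and
    chemical-potential ranges. Includes readers and writers for a tabular
    strain-model dialect, SBML level-3 FBC import, a community JSON format,
    synthetic community generators with analytically known Pareto fronts, and
    a reduced three-guild hot-spring phototrophic mat model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
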