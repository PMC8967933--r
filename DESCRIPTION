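Package: pftsim
Title: Demand-Constrained Cellular-Automata Land-Change Simulation and
    Plant Functional Type Subdivision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for scenario-based land-cover projection on
    regular rasters: calibration and harmonisation of coarse per-region land
    demand trajectories, a demand-constrained cellular-automata allocation
    engine with learned suitability surfaces, roulette selection and adaptive
    per-class inertia, bioclimatic subdivision of broad land classes into a
    20-class plant functional type scheme, and a map-comparison validation
    suite (overall accuracy, Cohen's kappa, figure of merit, block-change and
    class-proportion summaries). Includes a synthetic-world generator so every
    stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
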