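Package: sphingorheostat
Title: Sphingolipid Rheostat Kinetics, Metabolic Control Analysis and
    Likelihood-Based Model Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetic models of the sphingolipid rheostat
    (ceramide, sphingosine, sphingosine-1-phosphate, optionally sphinganine)
    in the embryonic zebrafish epidermis, with Metabolic Control Analysis of
    the core three-species scheme, condition-dependent apparent rates for a
    protease-mutant versus wild-type comparison, a negative-feedback
    hypothesis on de novo ceramide synthesis, maximum-likelihood calibration
    with per-species scaling factors and noise parameters, and a
    confidence-interval based comparison of feedback and no-feedback model
    variants on replicate-level lipidomics-style measurements. Includes a
    synthetic-data generator emulating the two-condition, two-time-point,
    four-replicate study design, and readers and writers for a strict subset
    of the PEtab parameter-estimation format.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
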