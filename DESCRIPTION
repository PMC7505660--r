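Package: asymreg
Title: Regulatory Asymmetry in Negatively Autoregulated Single-Input Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie), chemical master equation
    steady states, and deterministic mean-field models for a transcription
    factor that represses itself and an identically regulated target gene
    while competing decoy binding sites titrate the free pool.  Includes
    kinetic-rate calibration from operator binding energies, parameter-sweep
    drivers (network size, binding affinity, protein degradation, growth
    rate), a single-cell fluorescence analysis pipeline (crosstalk and
    background correction, binning, bootstrap), and a synthetic-cell
    generator with retained ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
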