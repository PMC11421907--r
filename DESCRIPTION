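Package: rangesse
Title: Extinction-Aware Ancestral Range Reconstruction on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State-dependent speciation-extinction modelling of geographic
    ranges on time-calibrated phylogenies. Generalizes the GeoSSE likelihood
    to an arbitrary number of areas with whole-lineage extinction and
    DEC- or DIVA-style cladogenesis, fits speciation and range-evolution
    rates by maximum likelihood with the lineage extinction rate fixed by
    the user, reconstructs marginal ancestral ranges and per-area species
    richness through time, and runs a four-extinction-scenario protocol
    calibrated against a standard birth-death fit. Includes an exact
    forward simulator of the same process for validation and synthetic
    data generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
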