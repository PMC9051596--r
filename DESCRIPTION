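Package: lutadsb
Title: Monte Carlo Simulation of Early DNA Double-Strand Breaks from
    In Vitro Lu-177-DOTATATE Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulation chain for early DNA double-strand-break
    (DSB) induction in planar cell cultures exposed to the beta and
    internal-conversion electron emissions of Lu-177. Provides parametric
    cell-compartment geometry (membrane, cytoplasm, Golgi, nucleus) for a
    50-cell planar population in a water medium cylinder, decay-scheme driven
    source sampling, simplified condensed-history electron transport with a
    phase space scored at the central nucleus, event-by-event specific-energy
    microdosimetry, a calibrated strand-break surrogate with opposite-strand
    DSB clustering, and the decay-weighted combination formula linking added
    activity to DSBs per cell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
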