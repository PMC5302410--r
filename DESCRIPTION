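Package: carenet
Title: Signed-Threshold Boolean Network Simulation of Cambium Regulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of deterministic Boolean gene-regulatory
    networks with signed-threshold update rules and clamped control inputs.
    Provides exhaustive attractor and basin-of-attraction enumeration over all
    initial conditions via a compiled functional-graph engine, basin-weighted
    ensemble activity statistics, in-silico knockout and constitutive-allele
    perturbation protocols, and binned chi-squared association analysis.
    Bundles CARENET, a 30-node model of hormonal control of cambium
    proliferation in plants, as the flagship network instance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
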