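Package: dsmcell
Title: Biophysical Simulation of Detrusor Smooth Muscle Cell Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Single-compartment biophysical model of a detrusor smooth muscle
    (DSM) cell. Nine Hodgkin-Huxley-type conductances, a ten-state Markov
    model of the large-conductance calcium-activated potassium (BK) channel,
    and a calcium-activated TRPM4 cation channel are assembled into the
    membrane equation and integrated with an operator-split implicit scheme.
    The package provides stimulus protocols (square current pulses and
    alpha-function synapses), action-potential feature extraction, rheobase
    bisection, conductance sensitivity sweeps, channel knockout experiments,
    Hill-parameter fitting of activation curves with a degrees-of-freedom
    corrected RMSE goodness-of-fit statistic, and bounded calibration of
    maximum conductances against whole-cell targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
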