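Package: optopallidum
Title: Analysis of Optogenetically Evoked Cortico-Pallidal Synaptic Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of optogenetic circuit-mapping
    experiments in the basal ganglia: detection and kinetic measurement of
    optically evoked excitatory postsynaptic currents (oEPSCs) from
    voltage-clamp sweeps, extraction of passive and active membrane
    properties from current-clamp recordings, axonal bouton-density
    normalization across nuclei, and cell-type connection-probability
    statistics with exact tests. Includes a leaky integrate-and-fire based
    synthetic-data generator with known ground truth so that every analysis
    stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
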