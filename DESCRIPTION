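Package: glomflow
Title: Olfactory Receptor Neuron Depolarizing Block and Glomerular Calcium
    Imaging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical simulation of olfactory receptor neuron (ORN)
    populations showing concentration-dependent depolarizing block, together
    with a calcium-imaging analysis pipeline for glomerular odor responses.
    Provides a four-compartment Hodgkin-Huxley ORN model with stochastic
    end-bulb noise and a piecewise odor-evoked receptor conductance,
    population peristimulus time histograms convolved with GCaMP6f kinetics,
    trace statistics (dF/F, adaptation index, signal-to-noise responsiveness,
    response maps, activation ranking), sparse linear decoding of glomerular
    population activity into percept classes, and a synthetic calcium-imaging
    cohort generator for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    EBImage,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
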