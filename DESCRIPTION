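Package: ttcasim
Title: Calcium Entry, Buffering and Diffusion in a Ventricular Myocyte
    T-Tubule Compartment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 3-D continuum model of depolarization-evoked Ca2+ entry,
    buffering and diffusion in a rat ventricular myocyte compartment
    containing one branched transverse tubule, with sarcoplasmic reticulum
    function inhibited. Includes a synthetic labeled tetrahedral mesh
    generator for the box-plus-t-tubule geometry, kinetic models of four
    Ca2+ buffers (Fluo-3, ATP, calmodulin, troponin C), sarcolemmal flux
    models (L-type Ca2+ current, Na+/Ca2+ exchange, background leak) with
    spatial redistribution scenarios, a finite-element reaction-diffusion
    solver with a well-mixed 0-D reduction, and analysis utilities
    (simulated confocal line scans, spatial Ca2+ heterogeneity, wavefront
    detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
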