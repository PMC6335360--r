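Package: omvsim
Title: Closed-Loop Simulation of Cerebellar Control of Saccadic Eye Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-based simulator of horizontal saccade generation and
    adaptation. A grouped brainstem burst generator with an internal
    displacement-integrator feedback loop drives a second-order oculomotor
    plant, while a bilateral cerebellar oculomotor vermis - mossy-fiber
    inputs, a sparse random granular-layer reservoir, plastic parallel
    fiber to Purkinje cell readouts, and caudal fastigial output nuclei -
    supplies online gain corrections. Parallel fiber to Purkinje cell
    weights are trained by derivative-free minimization of cumulative gaze
    error, and scripted experiment drivers reproduce main-sequence
    kinematics, Purkinje-population speed encoding, fastigial burst-pause
    patterns, and compensation for burst-amplitude variability.
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
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
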