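Package: contpsych
Title: Bayesian Participant Modelling for Two-Variable Continuous
    Psychophysics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for two-variable continuous
    psychophysics experiments in which a participant continuously nulls a
    perceptual deviation (for example induced motion of a target) while the
    computer randomly perturbs a second stimulus variable (the background
    direction).  Provides a generative "Bayesian participant" agent built
    from constant-gain Bayes-optimal filtering of random-walk stimuli, a
    two-variable perception rule in horizontal-component space, and a
    lagged damped-spring action system with motor noise; random-walk and
    step-walk stimulus generators with coverage selection; training-session
    system identification of the spring parameters, response lag and
    sensory noise; the inverse pipeline that converts noisy raw series into
    denoised "ideal" series by filtering and action-system inversion; a
    linear-accumulation model of motion adaptation with rate estimation;
    and binning, model-fitting and fit-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
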