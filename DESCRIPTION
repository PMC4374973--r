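Package: xtgate
Title: Adaptive Dopamine Gating of Prefrontal Working Memory in Executive
    Function Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Rate-coded neural simulation of prefrontal executive function
    with a temporal-difference (TD) dopamine gating mechanism.  Implements a
    k-winners-take-all settling network with an actively maintained
    prefrontal (PFC) layer, a linear TD critic whose error signal
    strengthens or destabilises PFC maintenance, a developmental training
    curriculum over factorial stimuli, a Wisconsin Card Sorting Test
    environment with perseveration scoring, a Stroop environment with
    settling-time reaction times, and group-level experiments in which
    multiplicative attenuation of the dopamine signal (kappa) dissociates
    cognitive flexibility (elevated WCST perseveration) from cognitive
    control (spared Stroop interference).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
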