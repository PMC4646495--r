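Package: hdclamp
Title: Virtual Teacher Simulations with the Human Dynamic Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulation and analysis of Human Dynamic Clamp
    experiments in which a model-driven "virtual teacher" -- a hybrid Van der
    Pol-Rayleigh oscillator with Haken-Kelso-Bunz (HKB) and Schoener-Kelso
    intentional coupling -- interacts bidirectionally with a rhythmically
    moving partner. Provides a synthetic partner with intrinsic in-phase and
    anti-phase coordination tendencies, the scanning and reward-based
    learning protocols, a Hilbert-transform relative-phase analysis pipeline
    with circular statistics, and histogram-based bidirectional transfer
    entropy estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
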