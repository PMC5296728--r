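Package: PulseDecode
Title: Information Transmission and Energetic Cost in Noisy Pulsatile Gene
    Regulation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a stochastically expressed gene whose
    transcription or mRNA degradation rate is driven by a pulsatile, noisy
    transcription-factor signal (amplitude- or frequency-modulated square
    waves with log-normal or gamma fluctuations).  Provides an exact
    stochastic simulator for the non-homogeneous birth-death process under
    piecewise-constant rates, the closed-form time-dependent Poisson solution
    of the chemical master equation and its mixture law under random rates,
    plug-in mutual-information estimation between the input rate and the
    mRNA output, Schnakenberg entropy-production (energetic-cost) estimation,
    and sweep pipelines for ON/OFF-time grids, signal-duration effects,
    information-energy correlation and noise-induced stochastic focusing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    Matrix,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
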