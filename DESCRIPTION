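Package: avburst
Title: Agent-Based Simulation of Anti-Vaccination Opinion Dynamics and
    Activity Bursts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-time agent-based model of anti-vaccination opinion
    dynamics in which patients, doctors, fixed-opinion initiators and
    infosphere messages interact through a biased-assimilation opinion
    update with emotionally asymmetric filtering.  Includes a compiled
    simulation engine with a bit-identical pure-R reference
    implementation, deterministic ensemble sweeps over the activism
    threshold and message-writing probability with sigmoid fits of the
    success ratio, burst statistics for spiky activity time series
    (rolling-median peak detection, lognormal, bounded power-law and
    log-Cauchy fits, time-rescaling matches), a synthetic burst-series
    generator with ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    MASS,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
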