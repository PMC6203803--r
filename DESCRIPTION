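Package: smkinetics
Title: Single-Molecule Membrane-Binding Kinetics and Spatial Bistability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying membrane-binding kinetics of peripheral
    membrane proteins from single-molecule TIRF trajectory data, and for
    quantifying spatial bistability of membrane lipid signalling domains.
    Includes a ground-truth trajectory simulator (continuous-time Markov
    state switching with per-state Brownian diffusion, photobleaching and
    localization noise), multi-exponential dissociation-curve fitting with
    photobleaching correction and intensity-weighted mean lifetimes,
    maximum-likelihood fitting of displacement-distribution mixtures with
    AIC model selection, two-state membrane-binding kinetic ODE fitting,
    and peripheral-kymograph and intensity-scatter polarity statistics
    (oscillation period by autocorrelation, aligned profile half-width,
    two-component Gaussian density fitting with bistability boundary
    estimation, co-localization probability, and chemotaxis metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
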