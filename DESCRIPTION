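Package: chaoscan
Title: Chaos Characterization of Periodically Forced Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterize deterministic chaos in periodically
    forced oscillators, motivated by sinusoidal redox forcing of
    mitochondrial oscillators. Provides a plug-in contract for
    user-supplied dynamical systems (continuous flows and discrete maps),
    built-in benchmark oscillators, steady-state integration with
    transient discard and uniform resampling, orbit/bifurcation diagrams
    with period-doubling detection, delay-coordinate phase-space
    reconstruction (average mutual information lag, false-nearest-neighbor
    dimension), dominant Lyapunov exponent estimation by the Wolf
    orbital-divergence method with an independent Benettin oracle,
    periodogram and entrainment analysis, and amplitude-by-period chaos
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
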