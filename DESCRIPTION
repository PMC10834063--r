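Package: memti
Title: Reduced-Order Simulation of Magnetoelectric Core-Shell Transducers
    for Magnetic Temporal Interference Neurostimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale modelling chain for a spherical magnetostrictive
    core (MetGlas) coated with a piezoelectric shell (AlN) driven by two
    high-frequency magnetic tones from a remote coil pair.  The nonlinear
    anhysteretic (Langevin) magnetostriction of the core demodulates the
    beat of the two tones into a genuine difference-frequency strain
    component; the shell converts strain into an open-circuit electric
    field whose low-frequency part is used to stimulate a Hodgkin-Huxley
    membrane model.  Provides material parameter sets, bias-sweep and
    optimal-bias analysis, free-sphere elastic eigenmode search, two-tone
    drive synthesis, power-spectral-density demodulation diagnostics,
    magnetoelectric coupling coefficients, and spike-threshold analysis
    of the demodulated stimulus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
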