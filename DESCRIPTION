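Package: mdtsim
Title: Magnetic Drug Targeting Simulation in Pulsatile Arterial Flow
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale two-dimensional simulator for magnetic drug targeting
    (MDT) in an arterial segment. Provides the analytic exterior field of a
    rectangular permanent magnet calibrated to a prescribed flux density and
    gradient at the vessel, generalized power-law (shear-thinning) blood
    rheology with a synthesized pulsatile inlet waveform, Brownian-dynamics
    trajectories of core/shell magnetic nanoparticles under magnetophoretic,
    Stokes drag and stochastic forces, and Monte Carlo estimates of the
    capture efficiency together with size and coating-thickness sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
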