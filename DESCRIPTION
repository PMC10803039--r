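Package: gliderev
Title: Mechanosensitive Reversal Control in Myxococcus xanthus Gliding
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic spatial model coupling the MglA/MglB/RomR cell
    polarity oscillator of Myxococcus xanthus to the state kinetics of the
    gliding (A-motility) machinery. Inactive, active and engaged motor
    populations evolve on a one-dimensional cell axis by reaction, advection
    and diffusion; motors exchange MglA with the polar pools, so that the
    motor engagement rate (a proxy for substrate stiffness) feeds back on
    the reversal frequency. Includes parameter sweeps, a two-dimensional
    (engagement x activation) phase diagram, and a qualitative screen of
    candidate networks by which the twitching (S-motility) machinery could
    regulate reversals through the gliding machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
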