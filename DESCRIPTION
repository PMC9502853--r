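Package: softsens
Title: Robust Adaptive Observer Soft Sensors for Second-Order Bioprocess Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Soft sensors for reaction rates in bioprocesses built on a robust
    adaptive state observer for second-order systems subject to persistent but
    bounded disturbances. Provides the observer with its dead-zone and
    saturation correction terms, closed-form analytics for the width of the
    convergence region of the estimation error (vertical asymptote, minimum
    point, transient envelope), and a simple algorithm for setting the observer
    gains from simulated disturbance bounds. Includes the Droop model of
    microalgae growth in a photobioreactor and its two second-order castings
    for estimating the specific substrate uptake rate from substrate
    measurements and the specific growth rate from biomass measurements,
    together with coupled plant-observer simulation, entry-time diagnostics,
    and numeric verification of the Lyapunov convergence claims.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
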