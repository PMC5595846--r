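Package: needledma
Title: Dynamic Mechanical Analysis for Needle-Based Ferrule-Top Micro-Indentation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital twin of a needle-based, load-controlled ferrule-top
    micro-indenter (cantilever force transducer, piezo actuator, Fabry-Perot
    interferometric readout, proportional-integral load feedback) together
    with the full analysis pipeline that converts oscillatory indentation
    recordings into frequency-dependent storage and loss shear moduli via
    the linearized Hertzian spherical-contact solution. Includes parametric
    linear-viscoelastic sample models (elastic, Kelvin-Voigt, standard
    linear solid, generalized Maxwell, springpot), a closed-loop measurement
    simulator that executes the approach / hold / frequency-sweep / retract
    protocol, single-frequency sinusoid extraction, quality-control flags,
    sweep aggregation, delimited-text recording files and a command-line
    interface. Validated by parameter recovery on simulated viscoelastic
    samples in the kilopascal range typical of soft biological tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
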