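Package: smartses
Title: Smart Error Sums: 2D-Correlation-Based Loss Functions for Curve Fitting
Version: 0.1.0
Authors@R:
    person("smartses", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Loss functions for nonlinear curve fitting that tolerate and
    correct multiplicative systematic errors. Instead of forcing modelled and
    measured curves to agree point by point (residual sum of squares), the
    "smart error sums" quantify how far hybrid two-dimensional correlation
    maps built from measured and modelled data deviate from the symmetry
    (synchronous) and antisymmetry (asynchronous) relations that hold for a
    single self-consistent series. Includes the full 2D correlation machinery
    (Hilbert-Noda transform, synchronous/asynchronous/phase-angle maps,
    two-trace variants), normalized cross-correlation losses, a Cauchy-type
    synthetic band generator with amplitude nonlinearity and peak-shift
    coupling, a deterministic fitting harness, a model-misspecification
    diagnostic based on asynchronous-map antisymmetry, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
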