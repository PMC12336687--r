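Package: hmeopt
Title: Design of Experiments and Pool-Constrained Bayesian Optimization for
    High-Moisture Extrusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tuning high-moisture extrusion process parameters
    (barrel temperature, water content, cooling-die temperature) so that the
    texture of a plant-protein extrudate approaches a reference product.
    Provides the three-factor Box-Behnken design with coded/actual unit
    conversion, a weighted-sum scalarization of texture-profile deviations
    from a reference, second-order response-surface fitting with full ANOVA
    (adjusted sums of squares, lack-of-fit, PRESS-based predictive R-squared)
    and optimum location, a Gaussian-process surrogate with expected-
    improvement acquisition restricted to a finite candidate pool, multi-seed
    convergence benchmarking of trials-to-convergence, validation-error
    reporting, and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
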