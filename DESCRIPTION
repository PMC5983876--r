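Package: orkin
Title: Odorant-Receptor Activation Kinetics and Combinatorial Odor Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for odorant-olfactory receptor (OR)
    dose-response data grounded in a minimal two-step kinetic model of
    G-protein coupled receptor activation. Fits Hill curves with a free
    Hill coefficient to per-pair dose-response measurements, classifies
    and quality-filters fits, and collapses curves onto the universal
    response function. Models the fitted parameter ensemble (Gaussian
    EC50 distribution, two-exponential efficacy mixture), inverts
    population fits into microscopic rate and binding constants via the
    triadic omega relation, and computes perception-level quantities:
    Weber ratios, binarized olfactory receptor neuron firing, and
    combinatorial odor-coding capacity. Includes a synthetic-data
    generator emulating the statistical structure of high-throughput
    odorant-OR screening panels so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    fitdistrplus,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
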