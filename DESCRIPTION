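Package: eeipm
Title: Evolutionarily Explicit Integral Projection Models for Quantitative Traits
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic per-generation simulation of the bivariate
    distribution of breeding values and environmental components of a
    quantitative trait under selection, genetic inheritance, and
    environment-driven dynamics (evolutionarily explicit Integral
    Projection Models, EE-IPMs). Provides a mid-point mesh discretization
    of (A, E) space, linear and exponential fitness functions, four
    treatments of the additive genetic variance (mid-parent convolution
    with segregation variance, a slope-0.5 Gaussian inheritance kernel,
    constant-variance Gaussian inheritance, and variance erosion),
    developmental noise with optional environmental trends and nongenetic
    inheritance, a full kernel-matrix projection engine and an equivalent
    fast vector engine, per-generation summaries (selection differentials,
    heritability, mean fitness), bundled model presets, an individual-based
    Monte-Carlo cross-check, and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
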