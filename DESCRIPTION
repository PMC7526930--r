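Package: chrysfoa
Title: Ensemble Learning and Fruit-Fly Optimization of Agrobacterium-Mediated
    Chrysanthemum Transformation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling and optimizing Agrobacterium-mediated genetic
    transformation protocols for chrysanthemum from a compiled literature
    database of GUS-reporter studies. Fits three individual regressors
    (a multi-layer perceptron, a radial basis function network, and a
    first-order Takagi-Sugeno adaptive neuro-fuzzy inference system) to
    eleven protocol factors, fuses them by bootstrap-aggregated (bagging)
    averaging, searches the fused response surface for the protocol that
    maximizes predicted transformation efficiency with a fruit-fly
    optimization algorithm, and ranks factor importance by
    variable-sensitivity-error / variable-sensitivity-ratio analysis.
    Includes a seeded synthetic-data generator with known ground truth for
    end-to-end validation, broom-style tidiers, and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
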