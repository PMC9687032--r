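Package: maeopt
Title: Response-Surface, Neural-Surrogate and Genetic-Algorithm
    Optimization of Microwave-Assisted Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for design-of-experiments optimization of
    microwave-assisted extraction of bioactive metabolites from brown
    seaweed. Implements the four-factor central composite design and its
    affine factor coding, ordinary-least-squares fitting of the full
    second-order response surface with ANOVA and lack-of-fit diagnostics,
    the standard model-validation metrics (MSE, RMSE, R2, AAD, SEP), a
    seeded Levenberg-Marquardt trained 4-16-4 feed-forward neural
    surrogate, bound-constrained genetic-algorithm and Derringer-Suich
    desirability multi-response optimization, a synthetic-data generator
    with parameter-recovery studies, and monoisotopic-mass /
    neutral-loss annotation of negative-mode LC-MS/MS metabolite peaks.
    Ships a complete 27-run extraction dataset, four published
    response-surface coefficient sets and a 79-compound annotation
    library as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
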