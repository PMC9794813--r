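Package: minime
Title: Desk-Scale Models of Metabolism and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build and solve desk-scale models of metabolism and gene
    expression (ME models) in which stoichiometric coefficients depend on
    the growth rate. Provides a seeded generator for a synthetic
    "mini-cell" organism with known ground truth, assembly of
    transcription, translation, tRNA-charging, complex-formation and
    translocation reactions with growth-rate-dependent coupling
    coefficients, growth maximization by bisection over linear-programming
    feasibility, gene-essentiality and carbon-substrate screens with
    confusion-matrix scoring, ethanol/folate/salt stress simulation with
    expression profiling and amino-acid demand attribution, and a protein
    secretion suite: growth and secretion kinetics estimation from batch
    time courses, near-optimal and forced-overexpression flux sampling,
    principal component analysis of flux samples, and amino-acid
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
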