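Package: qctf
Title: Quantitative Chromosome Transmission Fidelity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-dynamics estimation of per-division chromosome loss
    rates from two-timepoint GFP reporter flow-cytometry measurements, as
    used in quantitative chromosome transmission fidelity (qCTF) assays.
    Provides the forward branching model of marker-retaining (MC+) versus
    marker-lost (MC-) subpopulations, exact and approximate inverse
    estimators of the loss rate per division with a fitness-ratio
    correction, growth-curve fitting for doubling times, kernel-density
    gating of fluorescence event tables, a seeded stochastic simulator of
    the assay, and genome-scale screen statistics (replicate aggregation,
    rank-based tests, fold-change hit calling, candidate selection,
    enrichment tests) together with a synthetic-screen generator carrying
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
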