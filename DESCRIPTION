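Package: muevolab
Title: Antibiotic-Ramping Evolution Experiments on Cross-Feeding Bacterial Mutualisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis toolkit for serial-transfer evolution
    experiments in which obligately cross-feeding bacterial consortia and
    their monoculture controls are exposed to gradually increasing antibiotic
    concentrations. Implements threshold-zone sub-MIC determination from
    dose-response plates, doubling-then-linear antibiotic ramp schedules,
    a stochastic consumer-resource simulator of two amino-acid cross-feeding
    auxotrophs under serial transfer, growth-curve metrics and MIC calling,
    Kaplan-Meier survival with pairwise log-rank tests over lineage
    extinctions, Gaussian-mixture clustering of density trajectories with a
    Monte-Carlo cluster-composition permutation test, and colony-screen
    classification of auxotrophy reversion with Pearson chi-square
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    mclust,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite
Config/testthat/edition: 3
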