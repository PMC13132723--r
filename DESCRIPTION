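Package: repokin
Title: Repopulation Kinetics of CNS Macrophages After CSF-1R-Inhibitor Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of depletion-repopulation experiments on
    brain macrophage populations (microglia and CNS-associated macrophages).
    Converts per-animal cell densities into percent-of-control recovery with
    delta-method standard errors, fits a three-parameter logistic growth model
    to recovery over time and derives the time to 90% of control analytically,
    runs per-timepoint Welch tests with Bonferroni correction, estimates
    reporter-labeled fractions and hematopoietic-stem-cell-derived ontogeny
    fractions from complementary fate-mapping lines, tests cluster-composition
    shifts via arcsine square-root transformed proportions with
    Benjamini-Hochberg correction, implements the Brunner-Munzel rank test,
    and applies bulk RNA-seq gene prefilters (low-expression and
    substring/biotype/pathway blacklists). A seeded synthetic-cohort generator
    reproduces the statistical structure of the experimental design so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
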