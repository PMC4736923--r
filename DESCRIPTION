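Package: iristexture
Title: Characterization and Population Analysis of Iris Surface Features
Version: 0.1.0
Authors@R:
    person("Iris", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for grading human iris surface features (Fuchs' crypts,
    contraction furrows, Wolfflin nodules, pigment spots and conjunctival
    melanosis) from photograph annotations. Provides the annulus/quadrant
    geometry used to classify crypt marks and angular feature coverage, the
    ordinal grading rules, an implemented statistics suite (Goodman-Kruskal
    gamma, linear weighted kappa, chi-square homogeneity, grouped t-tests,
    one-way ANOVA), Hardy-Weinberg testing and maximum-likelihood
    proportional-odds ordinal regression with Nagelkerke R-squared, a seeded
    synthetic cohort and annotation generator, packaged published summary
    tables, and a command-line interface with a reproduction report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
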