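Package: cribuild
Title: Construction of PCA-Weighted Community Resilience Indices
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds area-level community resilience composite indices from an
    areas-by-indicators table: factorability testing (Kaiser-Meyer-Olkin,
    Bartlett's sphericity), principal components analysis on the correlation
    matrix with varimax rotation, Horn's parallel analysis for component
    retention, max-loading sub-index assignment, normalised squared-loading
    indicator weights, eigenvalue sub-index weights, and direction-aligned
    percentile-rank aggregation. Includes the unweighted BRIC-style variant
    for sensitivity analysis, deterministic imputation rules
    (population-weighted upper-tier disaggregation, prior-year substitution,
    peer-group means), geographic group comparisons (t-tests, one-way ANOVA),
    validation against a reference deprivation index, a seeded synthetic-data
    generator with known latent factor structure, and a command-line pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
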