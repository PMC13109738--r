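Package: dietniche
Title: Stomach-Content Dietary Composition and Trophic Niche Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of anuran stomach-content data: prolate-
    spheroid prey volumes, per-category dietary composition tables (frequency
    of occurrence, numeric and volumetric proportions, index of relative
    importance), Simpson and Shannon diversity, Levins standardized trophic
    niche breadth, Pianka pairwise niche overlap, and community-level
    comparison via Bray-Curtis dissimilarity, ANOSIM permutation tests and
    non-metric multidimensional scaling.  Includes a seeded synthetic
    stomach-content generator emulating the statistical structure of a
    three-species syntopic frog assemblage, long-format tabular I/O with
    validation, and reporting helpers that write table-style outputs with
    full provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
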