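Package: dyadtrans
Title: Dyad-Level Analysis of Microbial Transmission in Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of strain- and species-level microbial
    community sharing between paired individuals (mother-child dyads,
    couples, siblings) versus unrelated pairings. Implements a
    dependency-aware permutation test for comparing paired dissimilarities
    against the universe of cross-family pairings, together with community
    table filtering and rarefaction, membership- and abundance-based
    Bray-Curtis and Jaccard dissimilarities, Shannon diversity,
    shared-taxon fraction estimation, per-species strain comparisons with
    false discovery rate control, and a family-structured synthetic
    community generator with controllable transmission fidelity for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
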