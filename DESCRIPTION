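Package: emstools
Title: Elements of Metacommunity Structure for Binary Incidence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of species co-occurrence structure in metacommunities
    from site-by-species incidence matrices. Implements the three elements of
    metacommunity structure (coherence via embedded absences, species turnover
    via pairwise replacements, and boundary clumping via Morisita's index) on
    doubly ordered matrices, with fixed-sum binary null models and the full
    classification flowchart including quasi-structures; core/satellite and
    trophic-guild deconstruction of the species pool; a variance-reduction
    regression tree relating ordination scores to environmental gradients; and
    a seeded generator of synthetic metacommunities with known structure for
    method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan,
    withr
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
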