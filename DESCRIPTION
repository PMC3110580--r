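Package: traitgradient
Title: Trait-Gradient Analysis and Phylogenetic Comparative Methods for
    Community Trait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions species functional trait variation in ecological
    communities into within-community (alpha) and among-community (beta)
    components along a community trait gradient, estimates intraspecific
    trait-variation slopes, and tests for correlated evolution and
    phylogenetic signal with phylogenetically independent contrasts and
    Blomberg's K permutation tests. Includes Bray-Curtis/NMDS community
    ordination with a Monte-Carlo stress test, a seeded synthetic-data
    generator for community assembly with phylogenetically conserved
    traits, and an end-to-end pipeline producing publication-style
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    optparse,
    phangorn,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
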