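Package: mapforge
Title: Genetic Linkage Map Construction and Consensus Merging for RIL Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic linkage maps from recombinant inbred line (RIL)
    genotype matrices and merges maps from multiple populations into a single
    consensus map. Provides genotype quality control (heterozygote masking,
    missing-rate and allele-frequency filters), a two-point linkage engine with
    Haldane-Waddington RIL correction and Kosambi/Haldane mapping functions,
    recombinant-bin detection, LOD-threshold grouping, marker seriation by
    minimum sum of adjacent recombination fractions, consensus merging via
    weighted directed acyclic graphs with conflict resolution, monotone
    linearization and slope rescaling, plus map validation (Spearman order
    concordance, reference-map classification, marker-sharing Venn counts,
    interval profiles), multi-locus duplication and translocation analysis,
    and anchoring of markers to chromosomes and deletion bins from tabular
    homology hits. A multi-population RIL panel simulator with known true maps
    supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
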