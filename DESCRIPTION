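Package: topostrat
Title: Topological Stratification of Population Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mapper-based topological data analysis of genus-level
    microbiome abundance tables, with SAFE (spatial analysis of functional
    enrichment) permutation testing of host metadata and taxa on the
    resulting network, pairwise co-enrichment analysis, and per-node
    stratification. Includes a synthetic cohort generator that emulates
    multi-country, multi-study population datasets (unbalanced country
    groups, study-specific taxon panels with structural zeros, compositional
    abundances with planted country-taxon effects) so the full pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
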