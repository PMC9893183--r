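Package: kgcraft
Title: Construction and Validation of Disease-Centric Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to harmonize heterogeneous biomedical resources into a typed,
    disease-centric knowledge graph. Provides parsers and filter adapters for
    ontology (OBO) files and tabular resource exports, resolution of the overlap
    between phenotype and disease vocabularies, a two-stage disease entity
    grouping algorithm combining suffix-driven string matching with name-embedding
    similarity, deterministic graph assembly with largest-connected-component
    extraction, attachment of clinical text features to drug and disease nodes,
    and a network-proximity permutation test for drug repurposing. A synthetic
    fixture generator emulates every consumed format at miniature scale with
    planted ground truth so the full pipeline runs without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    xml2
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
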