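Package: tfcompendium
Title: Curation of a Transcription-Factor Compendium from Domain, Orthology,
    Interaction and Expression Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a manually-curated repertoire of sequence-specific
    DNA-binding transcription factors (TFs) for a target species from tabular
    annotation inputs: a reliable DNA-binding-domain (DBD) registry compiled by
    intersecting TF databases against a reference census, InterPro-based gene
    screening, an orthology- and domain-arrangement-driven evidence-class
    cascade, DBD family classification, cross-species conservation grouping,
    transcription-cofactor identification from molecular-interaction records
    filtered by interaction type and Gene Ontology evidence, and tissue
    expression/coexpression summaries from FPKM matrices. Ships a seeded
    synthetic-annotation generator with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
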