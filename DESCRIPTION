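Package: afdomain
Title: Domain Parsing and Six-Category Classification for Predicted Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses AlphaFold-style predicted protein models into structural
    domains using the predicted aligned error (PAE) matrix and per-residue
    pLDDT confidence, classifies every residue into one of six region
    categories (assigned, unassigned, partial, simple, flexible,
    low-confidence), summarises per-proteome coverage, tallies domain
    populations by homologous group with chi-squared enrichment testing and
    Bonferroni correction, builds redundancy-reduced sequence representative
    sets by greedy incremental clustering, and compares parsed domains
    against sequence-annotation intervals. Ships a synthetic-data generator
    that emulates predicted-model inputs (block-structured PAE, bimodal
    pLDDT, ideal secondary-structure geometry, mock homology-hit tables)
    with per-residue ground-truth labels for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    glmnet,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
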