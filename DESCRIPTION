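Package: argenrich
Title: Enrichment Calling and Site Classification for Side-Chain
    Arginylation Proteomics
Version: 0.1.0
Authors@R:
    person("ArgEnrich", "Developers", email = "argenrich@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pan-arginylation immunoaffinity pulldown
    proteomics with a knockout negative control. Implements quality
    filtering, log transformation and per-sample normalization of protein
    intensity tables, missing-not-at-random downshift imputation,
    input-normalized fold changes with paired t-tests for wildtype versus
    Ate1-knockout enrichment calling, mapping and confidence classification
    of side-chain arginylation sites from modified-peptide evidence
    (localization probability, posterior error probability, knockout
    exclusivity, preceded-by-Arg artifact removal), and Markov clustering
    of weighted protein-interaction graphs. Includes a synthetic-data
    generator with truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
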