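Package: oncovoice
Title: Conversational Exploration of Cancer Cohort Genomics with Noisy-Term Resolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale conversational engine for cohort cancer genomics.
    Resolves noisy speech-to-text transcriptions of gene symbols, cancer
    types and data types to canonical terms through a three-stage chain
    (exact matching, crowdsourced-utterance lookup, and a random-forest
    classifier over character n-gram, phonetic and length features),
    maintains a three-slot dialogue state (gene, cancer type, data type),
    and answers queries against a harmonized knowledge base built from
    multi-caller somatic mutation tables, gene-level copy-number categories
    and expression matrices. Includes seeded generators for synthetic
    cohorts and pronunciation corpora with known planted structure, plus a
    text REPL and batch subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
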