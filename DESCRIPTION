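Package: belpipe
Title: Rule-Based Extraction of Biological Expression Language Statements
    from Sentences
Version: 0.1.0
Authors@R:
    person("belpipe", "maintainers", email = "belpipe@example.org",
           role = c("aut", "cre"))
Description: A pipeline for extracting causal Biological Expression Language
    (BEL) statements from single biomedical sentences. Provides dictionary
    maximum-matching named entity recognition with heuristic surface
    normalization, grounding of mentions to namespace identifiers with a
    homolog-to-human disambiguation ladder for proteins, pattern-based
    classification of molecular-activity functions, a rule-based semantic
    role labeler operating on Penn Treebank constituency parses, assembly of
    subject-verb-object tuples into increases/decreases statements with
    keyword polarity adjustment, and a scorer that compares predicted
    against gold statements at term, function, relation and full-statement
    level. Ships worked-example fixtures and a synthetic corpus generator
    with known gold structure so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
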