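Package: phenorec
Title: Phenotype Concept Recognition with Conditional Random Fields and
    Validation Rules
Version: 0.1.0
Authors@R:
    person("phenorec", "maintainers", email = "phenorec@example.org",
           role = c("aut", "cre"))
Description: Recognizes Human Phenotype Ontology (HPO) terms in biomedical
    abstracts. Combines a linear-chain conditional random field sequence
    labeler with a rich token feature set (linguistic, orthographic,
    morphological, context, lexical and cluster features) and a
    dictionary-plus-rules validation stage that removes false positives,
    recovers missed mentions and adjusts entity boundaries. Includes
    readers and writers for gold-standard corpora with character-offset
    annotations, an OBO ontology loader, exact-span micro-averaged
    evaluation, a false-positive filter experiment, tooling to extend a
    gold-standard corpus with consistent automatic annotations, and a
    synthetic-fixture generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
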