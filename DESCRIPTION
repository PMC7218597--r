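Package: combokg
Title: Discovering Combination Drug Therapies from Semantic Predications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines conclusive claims from biomedical abstracts, filters
    SemRep-style subject-predicate-object predications to treatment
    assertions with drug subjects and disease objects, groups same-claim
    predications that share a predicate and disease object but differ in
    drug subject into combination-therapy candidates, and assembles the
    candidates into a combination-centric knowledge graph with claim-level
    evidence. Includes MeSH tree-based filters for overly generic concepts
    (pharmacologic actions, top-level disease classes), a synthetic corpus
    generator with planted ground truth for end-to-end validation, and
    command-line entry points for each pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
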