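Package: tbkg
Title: Tumor-Biomarker Knowledge Graphs for Explainable Adverse Drug
    Reaction Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a typed, weighted knowledge graph with tumor, biomarker,
    drug and adverse drug reaction (ADR) nodes from literature abstracts.
    Entities are tagged with a dictionary longest-match tagger, turned into a
    binary document-entity incidence matrix, and relations between entity
    types are scored with a Bernoulli naive-Bayes importance measure (the
    base-2 log ratio of a feature's conditional presence probability given
    the target's presence versus absence). Candidate drug-ADR pairs are
    ranked and every pair carries its explanation paths through biomarker and
    tumor nodes, enumerated by depth-first search. Includes a co-occurrence
    baseline, agreement statistics (Cohen's kappa, sensitivity, specificity)
    against a gold ADR list, a planted-truth synthetic corpus generator for
    end-to-end testing without licensed corpora, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    xml2,
    yaml,
    stats,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
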