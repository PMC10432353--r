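Package: noteshift
Title: Domain-Shift Auditing for Clinical Note Information Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing how clinical text-extraction and
    classification systems degrade across care contexts. Provides a
    synthetic clinical-note corpus generator with triplicate annotator
    simulation and a similarity-dependent predictor; passage isolation
    under institution-specific dialect rules; majority-vote annotation
    merging with Cohen's kappa, span-overlap F1 and percent-agreement
    metrics; kernel/context decomposition with Levenshtein and
    embedding-cosine similarity profiling against a training corpus; and
    correctness-stratified Mann-Whitney comparisons with Q-Q tables
    against the within-training reference distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
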