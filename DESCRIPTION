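Package: negev
Title: Identification of Negated Bio-Events in Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting negated bio-events given gold-standard event
    annotations in BioNLP-ST-style standoff format. Provides readers and
    writers for standoff annotation triples (.txt/.a1/.a2), curated negation
    cue lexicons with deactivation logic for the cue "not", constituency and
    dependency primitives (S/VP/NP-command relations, dependency paths,
    syntactic cue scope), engineered lexical, semantic, syntactic,
    lexico-semantic, dependency and constituency features, polarity
    classifiers with stratified cross-validation and micro-averaged
    precision/recall/F reporting, and a deterministic synthetic corpus
    generator that plants the five main types of event negation at
    configurable rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    rpart,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
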