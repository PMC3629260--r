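Package: asmevents
Title: Approximate Subgraph Matching for Biomedical Event Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts biomedical events and binary relations from
    dependency-parsed sentences by approximate subgraph matching. Graph
    rules are induced from annotated events as shortest dependency path
    unions and individual trigger-to-argument paths, generalized over
    pre-annotated biological entities, and matched against unseen sentence
    graphs under a tolerance-thresholded subgraph distance that penalizes
    structural, edge-label and edge-direction differences. Nested events
    are assembled bottom-up, unreliable rules are pruned by a
    leave-origin-out true-to-false-positive ratio, and matching parameters
    can be tuned by an integer genetic algorithm. Includes readers and
    writers for BioNLP-ST standoff annotations, Stanford-dependency triple
    and CoNLL parse formats, a seeded synthetic corpus generator with
    controlled graph perturbations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
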