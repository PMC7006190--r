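Package: bioevex
Title: Joint Biomedical Event Extraction with a Penalty-Minimising
    Combination Strategy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts (possibly nested) biomedical events from annotated
    text in BioNLP-ST standoff format. A shared sentence encoder
    (character-level CNN plus entity-aware bidirectional LSTM) feeds three
    jointly trained heads: a greedy BILOU trigger labeller with
    previous-label feedback and scheduled sampling, a relation classifier
    over pooled source/middle/destination segment features with a distance
    embedding, and an event-evaluation head that scores schema-valid
    candidate event structures via role-label sequences. Final events are
    assembled by a combination strategy that minimises a support-waste /
    support-lacking penalty, with a brute-force oracle for small
    instances, topological handling of nested candidates, an event-loop
    detector and modification (Negation/Speculation) assignment. Includes
    standoff corpus I/O, approximate span and recursive event matching
    metrics, an extraction-error typology, and a seeded generator of
    schema-conforming synthetic corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
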