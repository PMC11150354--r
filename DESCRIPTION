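Package: dialograph
Title: Graph-Based Representations of Clinical Interview Transcripts for
    Depression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds graph-based representations of two-speaker clinical
    interview transcripts and trains graph neural classifiers for binary
    depression screening from them. Supports sentence-similarity graphs and
    NMF keyword-correlation graphs, each in a single-graph baseline form and
    a multi-view form that splits the interview into therapist and patient
    views joined by question-answer cross edges. Includes a deterministic
    sentence encoder for fully offline work, a synthetic interview-corpus
    generator with class-dependent dialogue structure, graph convolutional
    network models with attention pooling and cross-attention view fusion,
    an imbalance-aware training and evaluation protocol (macro-F1, UAR),
    and DOT/GraphML visual summaries of the graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    igraph,
    jsonlite,
    pracma,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
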