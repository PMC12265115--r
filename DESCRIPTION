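Package: BoolMerge
Title: Merging and Evaluating Boolean Gene-Regulatory-Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to compose independently published Boolean logical models
    of gene regulation into a single executable model. Provides a rule grammar
    and expression engine for Boolean update functions, three deterministic
    rule-composition strategies (OR, AND, and Inhibitor Wins) with per-node
    overrides, gene-symbol harmonization against offline mapping tables,
    SBML-qual and bnet import/export, exact synchronous and asynchronous
    attractor detection, attractor-pattern clustering by Hamming distance,
    mutation clamping, and a phenotype-based network score. A seeded
    generator of random Boolean networks and overlapping model pairs makes
    every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
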