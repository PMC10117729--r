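Package: fesnet
Title: Multivalued Logical Modeling of Fe-S Cluster Biogenesis Regulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Qualitative (Thomas-formalism) logical modeling toolkit built
    around the regulatory network controlling iron-sulfur cluster biogenesis
    in Escherichia coli. Provides a generic multivalued logical-model engine
    with unitary asynchronous updating, full state-transition-graph
    construction over clamped subspaces, attractor detection as terminal
    strongly connected components, per-node asymptotic summaries, module-level
    behavior classification, and in-silico knock-out screens that predict
    growth-defect conditions. Ships the 14-node Fe-S biogenesis network
    (Isc/Suf machineries, IscR, Fur, RyhB, OxyR, Hpx) together with a random
    multivalued network generator and an independent brute-force attractor
    oracle for validating the engine.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
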