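Package: speechdisorg
Title: Speech Graph Connectedness Analysis of Formal Thought Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents time-limited verbal reports as directed word-trajectory
    multigraphs and quantifies formal thought disorder from their
    connectedness. Computes edge counts and largest weakly/strongly connected
    components, z-scores each report against an empirical null of
    word-shuffled surrogate graphs, combines attributes into a
    symptom-anchored Disorganization Index by collinearity-pruned multilinear
    regression, and classifies diagnosis and negative-symptom severity with a
    cross-validated Gaussian Naive Bayes classifier. Includes a synthetic
    transcript and cohort generator with controllable word-recurrence
    structure so the whole pipeline can be exercised and calibrated without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
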