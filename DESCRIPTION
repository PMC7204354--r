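Package: ducg
Title: Differential Diagnostic Reasoning with Dynamic Uncertain Causality Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An inference engine for dynamic uncertain causality graphs
    (DUCG), a probabilistic causal graphical model for differential
    diagnosis. Provides a JSON model format with typed variables (root
    causes, observables, logic gates, default causes), evidence-driven
    graph simplification with pruning and causality tracking, symbolic
    weighted logic event expansion with exclusion, concurrency and
    dummy-basic-variable handling for mutually exclusive root causes,
    hypothesis-space construction, state-probability and ranked
    independent-probability computation, an exact joint-enumeration
    oracle for validation on small models, a synthetic model generator,
    Graphviz DOT export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
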