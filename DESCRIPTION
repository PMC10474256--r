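Package: netlens
Title: Tracing, Visualizing and Validating the Forward Pass of Neural Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustively logs every tensor operation executed during one
    forward pass of a neural-network model written in the package's
    array-operation framework, assembles and post-processes the full
    computational graph (orphan trimming, graph distances, conditional-branch
    inference, module-containment repair, recurrent-layer grouping), assigns a
    uniform layer nomenclature, algorithmically validates saved activations by
    re-execution, and renders rolled or unrolled Graphviz DOT visualizations at
    a chosen module-nesting depth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
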