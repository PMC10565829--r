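Package: rxnscheme
Title: Parsing Chemical Reaction Scheme Images into Reaction Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine reading of raster images of chemical reaction
    schemes. Includes a schema-driven generator of artificial annotated schemes
    ("scheme engineer") for training and testing, connected-component arrow
    proposal and a two-branch convolutional arrow detector/classifier trained
    with a combined binary and multiclass cross-entropy loss, a pluggable region
    detector for diagrams, labels and conditions text (learned backend plus a
    ground-truth oracle), symbolic postprocessing (dilation-based diagram
    completion, text-region reclassification and pairing), arrow geometry
    recovery (rotated-rectangle direction, center of mass, curly-arrow
    endpoints), reconstruction of the reaction scheme as a machine-readable
    graph, and detection/graph evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
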