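Package: minichi
Title: Desk-Scale Canonical Chemical Identifiers and Reliability Audits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for layered chemical identifier strings
    in the InChI family: a parser and serializer for the layered text format
    (standard '1S' and beta '1B' dialects, including the v1.06 polymer '/z'
    layer and 'Zz' pseudo-atoms), a Molfile V2000 reader/writer, a reference
    canonical molecular-graph labeler built on equitable partition refinement
    with an exhaustive small-graph oracle, tetrahedral parity bookkeeping with
    2D perception rules (near-collinearity rejection and a large-ring
    relaxation), structural-repeat-unit polymer canonicalization, and a
    reliability-audit harness that fuzzes identifier generators with random
    atom renumberings and classifies imperfections (generation failure,
    collision, numbering instability, version difference).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
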