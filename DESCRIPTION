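Package: bubblegrid
Title: Bubble Heatmaps for Nightingale Health Metabolomics Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Displays association results as grids of bubbles that encode
    two numeric values per cell: fill colour shows a signed effect estimate
    on a symmetric diverging scale and circle size shows the (optionally
    capped) -log10 P-value. Packaged variable catalogs lay out the 225-,
    249- and 251-variable Nightingale Health NMR metabolomics panels,
    including the block of 12 measures repeated across 14 lipoprotein
    subclasses, as a single composed multi-panel figure; user-defined
    catalogs support arbitrary grids and layouts. Figures are serialised
    to deterministic SVG or drawn to PDF/PNG, and a command-line interface
    wraps the full workflow. A seeded generator produces synthetic
    association results emulating a CETP genetic-score analysis for
    examples and tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    grid,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
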