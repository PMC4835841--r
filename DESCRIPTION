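Package: genotrellis
Title: Genome-Level Trellis Layouts and Multi-Track Plotting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A layout engine and track-drawing API for genome-wide Trellis
    figures. Allocates per-chromosome (or per-region), per-track panels under
    proportional one-row, equal-width grid, length-optimized grid and compact
    non-rectangular layout styles; iterates user-defined or built-in panel
    functions over genomic categories with automatic per-category data
    subsetting and clipping; computes rainfall neighbour distances and windowed
    coverage density; reads chrom.sizes, BED/bedGraph and UCSC cytoband tables;
    renders deterministic SVG and exports layout geometry as JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
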