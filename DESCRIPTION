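Package: adiposize
Title: Calibrated Adipocyte Counting, Sizing and Colour-Area Quantification
    for Histology Images
Version: 0.1.0
Authors@R:
    person("Adiposize", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scriptable analysis of microscopic images of adipose tissue.
    Detects adipocytes in H&E-style sections by contour tracing on a
    binarized image (Moore border following with collinear chain
    compression), converts pixel counts to square microns via a
    microns-per-pixel calibration (read from TIFF metadata or derived from
    a measured scale bar), and supports the usual curation steps: size
    limits, border-cell exclusion, and reversible point-click toggling of
    individual objects. Also quantifies the area fraction of RGB colour
    ranges in stained images, splits and recombines fluorescent channels,
    builds size histograms, compares two analyses with Pearson
    correlation and percent differences, and exports results to CSV or
    xlsx. Includes a synthetic tissue-image generator (Voronoi mosaics
    with known per-cell areas, haze, dust, scratches) so the whole
    pipeline is testable without real slides, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    png,
    stats,
    tools,
    utils,
    zip
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
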