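Package: ctlapse
Title: 4D Micro-CT Time-Lapse Assembly and Plant Organ Movement Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns weekly micro-CT reconstructions of living plants into aligned
    3D time-lapse videos and quantifies organ movement. Reads per-timepoint
    grayscale slice stacks, harmonizes them onto a common voxel grid, rigidly
    registers every timepoint to a reference by normalized cross-correlation
    with multi-resolution search, bins volumes, renders annotated turntable
    maximum-intensity projections, and assembles them into a video. A movement
    module turns organ orientation and axial-roll angle series into classified
    bending, twisting and resupination events, and a synthetic phantom
    generator provides ground-truth growing, bending and rolling root volumes
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    png,
    readr,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
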