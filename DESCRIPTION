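Package: brainNetVis
Title: Multi-Panel 3D Visualization of Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Composes an anatomical template volume, a node set and an edge set
    into multi-panel, publication-quality 3D network figures. Templates are
    skull-stripped or segmented NIfTI volumes rendered in glass, surface,
    filled or cloudy styles; nodes come from coordinate tables, integer-labeled
    parcellation volumes or atlas descriptors, and edges from adjacency
    matrices or edge lists. Aesthetics (color, size, highlighting) are driven
    declaratively by table columns, anatomical view presets and rotation-frame
    sequences define the panel grid, and a force-directed spring-layout panel
    can sit alongside the anatomical views. Figures export to PNG or SVG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    RNifti,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
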