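Package: cytomorph
Title: Quantitative Image Cytometry for Spheroid, Organoid, Tube-Formation
    and Cell-Migration Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reproducible, scriptable re-implementations of the image
    cytometry pipelines used in prostate-cancer 3D culture studies:
    stellate-spheroid invasion scoring (inner core, outer core and
    peripheral invading-cell areas plus inner-core circularity),
    live/dead organoid-field cytometry with dual-engine punctate
    dead-cell detection, skeleton-graph quantification of endothelial
    tube networks with a control-normalised angiogenesis index, spot
    detection with gap-closing track linking and 3D surface
    morphometry, and closed-form scalar scores (caliper tumour volume,
    composite immunohistochemistry score). A synthetic-phantom
    generator plants ground-truthed spheroids, organoid fields, tube
    lattices and particle movies so every stage is verifiable without
    external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
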