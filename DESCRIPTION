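Package: scutoidr
Title: Scutoid Detection and 3D Packing Morphometrics for Curved Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects scutoids (apico-basal T1 intercalations) in labelled 3D
    segmentation volumes of monolayered spheroidal epithelia and computes the
    associated cell- and tissue-scale morphometric panel: apical/basal layer
    extraction by directional z-scans, dilation-based neighbour graphs, cell
    volume, convexity ratio, cell height, cell density, opening areas,
    ellipsoid surface fits with principal curvatures, surface ratio
    anisotropy and tissue surface ratio. Includes matched 3D Voronoi null
    constructions for comparing observed packing against a static geometric
    model, time-resolved scutoid onset/duration analysis relative to cell
    division, and a synthetic spheroidal-epithelium generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
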