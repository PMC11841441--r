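Package: perfuseR
Title: Flow, Transport and Image-Derived Metrics for Perfusable Vascularized Hydrogel Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for characterizing bioprinted, perfusable
    vascularized hydrogel constructs. Provides a reduced-order axisymmetric
    solver for laminar channel flow coupled to Brinkman porous-media seepage
    in a GelMA matrix (wall shear stress, parametric flow-rate sweeps) and
    for transient solute transport from the channel into the matrix
    (time-to-target concentration); FRAP diffusion-coefficient estimation
    from recovery curves; extrusion-printability, porosity/pore-size,
    LIVE/DEAD viability and vascular-permeability image metrics; endothelial
    network (tube-formation) quantification via skeletonization; and
    deterministic synthetic-image generators with known ground truth for
    every assay, so the whole pipeline is testable without raw microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    igraph,
    minpack.lm,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
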