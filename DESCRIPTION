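Package: parasurf
Title: C2 Parametric B-Spline Surface Fitting to Segmented Image Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reconstructs compact, twice continuously differentiable
    tensor-product cubic B-spline surfaces from polygonal surfaces
    extracted from segmented 3D grayscale image volumes (for example
    micro-CT of heart ventricles).  The pipeline extracts boundary quad or
    triangle meshes by thresholding, projects a user-delimited patch
    one-to-one onto a rectangular parametric plane by a Tutte-type
    neighbour-average embedding, regularizes the projected mesh for
    polygon area and edge length by minimizing a Jacobian deformation
    energy, fits the spline with an optional curvature/twist stiffness
    penalty and exact edge clamping to a spline curve, and reports
    closest point-to-surface distances computed by companion-matrix
    quintic root finding with Newton refinement.  Voxelized analytic
    phantoms (ball, bumpy hemisphere, hemisphere with a papillary-like
    protrusion) make the whole pipeline runnable and testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
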