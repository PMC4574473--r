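Package: epishear
Title: Triangle-Method Decomposition of Epithelial Tissue Shear
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the large-scale deformation of a tracked epithelial
    cell network into its cellular contributions: cell shape change, cell
    neighbor exchanges (T1 transitions), cell divisions, cell extrusions
    (T2 transitions), and correlation effects. The tissue is tiled with
    triangles spanned by neighboring cell centers; each triangle's state is
    an area, an orientation and a nematic elongation tensor, and
    topological transitions contribute through discontinuous retriangulation
    jumps in mean elongation. Also included: quantification of tissue
    stress from the anisotropic recoil of circular laser ablations, a
    delayed-viscoelastic constitutive law for shear caused by topological
    changes with spiral-signature fitting, a two-rectangle (hinge/blade)
    continuum model of pupal wing morphogenesis with boundary springs and
    friction, and a synthetic tracked-tissue generator with scripted
    deformations and topological events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RSQLite,
    DBI
Config/testthat/edition: 3
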