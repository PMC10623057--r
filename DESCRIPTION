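Package: sicsfract
Title: Fracture Mechanics of Corneal Incisions in Small-Incision Cataract Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element fracture analysis of straight, chevron, and frown
    corneal incisions used in small-incision cataract surgery. Builds
    conforming plane-stress meshes with the incision represented as a seam
    (duplicated node pairs) and spider-web contour rings at each crack tip,
    solves the linear elastic problem under equibiaxial edge traction,
    computes the energy release rate at the incision tips by equivalent-domain
    J-integrals averaged over contour rings, and applies the Griffith
    criterion. Includes the study protocols: load calibration to a target
    mid-incision opening (the intraocular-lens injector diameter), incision
    shape sweeps, critical incision length inversion, and an orthotropic
    material table, together with closed-form linear elastic fracture
    mechanics oracles for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
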