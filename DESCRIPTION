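Package: tissuecut
Title: Coupled Mesh-Meshless Simulation of Soft-Tissue Cutting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch simulator for surgical cutting of soft tissue using a
    coupled surface-mesh / internal-meshless model. The tissue surface is a
    triangle mesh cut along quadratic Bezier incision curves; the interior is
    a set of meshless point elements deformed by moving-least-squares (MLS)
    displacement-gradient elasticity with Green strain and explicit time
    integration. The two representations are coupled through interpolated
    virtual boundary points that carry the surface opening into the meshless
    solve as prescribed displacements. Includes level-set classification of
    cutting-affected point elements via signed distances to the blade and
    vertical planes, an oscillating haptic force-feedback model with an
    empirical double-Gaussian cutting-force fit, synthetic model generators
    (box, ellipsoid) with equal-distance interior point interpolation, and
    plain-text mesh and point I/O (OBJ, OFF, PLY, CSV, XYZ).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
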