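Package: spinlyo
Title: Intra-Vial Primary-Drying Kinetics from Time-Resolved Micro-CT of
    Spin-Frozen Vials
Version: 0.1.0
Authors@R:
    person("spinlyo", "developers", email = "spinlyo@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved (4D) micro-computed
    tomography of spin freeze-dried pharmaceutical vials. Provides a
    synthetic phantom generator with known ground truth, conversion of
    cartesian greyscale volumes to a cylindrical (r, phi, h) segmentation,
    frozen-layer thresholding and sublimation-front extraction,
    sublimation-direction diagnostics, regression of local dried-product
    mass-transfer resistance Rp as a function of dried-layer thickness,
    a coupled heat/mass-balance simulator of the intra-vial primary-drying
    endpoint distribution, and an emulated thermal-imaging verification
    with endpoint-distribution comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
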