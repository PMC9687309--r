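Package: trabrec
Title: Topology-Optimization-Based Trabecular Bone Microstructure Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs trabecular bone microstructure at 50 micrometre
    resolution from low-resolution (600 micrometre) 2D bone density images by
    compliance-based topology optimization under a density-deviation
    constraint. Implements both the conventional approach, which refines and
    solves the full global finite-element model at every design update, and a
    localized approach that extracts a region of interest and estimates
    physiological local loads on its cut boundary by static condensation,
    reducing each design update to a small local problem. Includes a
    structured-grid plane-stress finite-element core, a Method of Moving
    Asymptotes optimizer, a synthetic proximal-femur phantom with
    physiological hip-contact and abductor load cases, and 2D trabecular
    morphometry (BV/TV, Tb.Th, Tb.Sp, Tb.N, alignment angle) for comparing
    reconstructions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    jsonlite,
    tiff,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
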