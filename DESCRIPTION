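Package: fxsrec
Title: Single-Particle Structure Determination from Fluctuation X-Ray Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete workflow for ab initio single-particle structure
    determination from fluctuation X-ray scattering (FXS) data. Simulates
    dilute-ensemble diffraction snapshots of analytic sphere-cluster phantoms,
    accumulates the mask-aware averaged two-point angular cross-correlation
    function, extracts rotational invariants (circular orders B_n in 2D,
    spherical orders B_l in 3D, including a fast triangular back-substitution
    extraction valid under Ewald-sphere curvature), reconstructs real-space
    electron density by multitiered iterative phase retrieval (MTIP) with
    error-reduction/hybrid input-output updates, shrinkwrap support refinement
    and midpoint-rule Hankel transforms, and aligns, averages and scores
    reconstructions including phase-retrieval transfer function resolution
    estimates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
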