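Package: acltunnel
Title: Semi-Automated 3D CT Morphometry of ACL Reconstruction Bone Tunnels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring bone-tunnel geometry and post-operative
    tunnel widening in anterior cruciate ligament (ACL) reconstructed knees
    from segmented computed-tomography label volumes. Implements best-fit
    cylinder and cross-sectional circle measurements at the tunnel aperture
    and 10 mm from the joint line, robust filtering of interference-screw
    artifacts, inter-tunnel communication detection, and the statistical
    layer used in tunnel-widening studies: paired and Welch t-tests,
    intraclass correlation ICC(2,1) with nonparametric bootstrap confidence
    intervals, and a priori power analysis for paired designs. Ships a
    ground-truthed synthetic phantom generator (drilled tunnels on
    anisotropic CT-like voxel grids, widening profiles, screw-tip artifacts,
    rater perturbations, converging tunnel pairs) so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
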