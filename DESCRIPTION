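Package: dendrotomo
Title: Line-Trajectory X-Ray Tomography for Non-Invasive Dendrochronology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for retrieving tree-ring width series from large wooden
    objects by line-trajectory (LT) cone-beam X-ray tomography. The object is
    translated linearly between a static source and detector; the resulting
    limited-angle projection data are reconstructed with the simultaneous
    iterative reconstruction technique (SIRT) over line or circular
    trajectories, supporting cuboid (anisotropic) voxels. Includes a
    two-phase (earlywood/latewood) tree-ring phantom generator with
    controllable ring tilt, flat-/dark-field correction, nail-ruler geometry
    calibration, transverse slice extraction with a sharpness ranking,
    automated ring-boundary detection along measurement paths, Tucson RWL
    and CSV ring-width input/output, and dendrochronological crossdating
    statistics: the Baillie-Pilcher t-value (TBP), Gleichlaeufigkeit (Gl)
    with its normal-approximation significance, mean inter-series
    correlation (rbar), and a sliding-offset crossdating search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
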