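Package: aaafc
Title: Patient-Specific Abdominal Aortic Aneurysm Geometry Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts three-dimensional abdominal aortic aneurysm (AAA)
    geometry from longitudinal surface meshes. Lumen and outer-wall
    surfaces from serial imaging sessions are unwrapped onto a
    centerline-anchored cylindrical (z, theta) lattice with one-to-one
    node correspondence over time; node-wise linear mixed-effects models
    with patient-level fixed effects and node-level random intercepts and
    slopes are fitted by maximum likelihood; predicted radii and
    centerlines are back-projected to yield a Cartesian forecast surface
    at any target time. Includes spatial-similarity evaluation via the
    95th-percentile Hausdorff distance in centerline, unwrapped and
    reconstructed spaces, hydraulic-diameter and volume scalars, a
    synthetic longitudinal aneurysm generator for validation, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
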