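Package: linacclear
Title: Patient-Specific Linac Collision Clearance Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates C-arm linear-accelerator gantry, couch and collimator
    motion against patient body and couch triangle meshes to predict collision
    risk during treatment planning. Provides oriented-bounding-box binary-tree
    collision detection with separating-axis overlap tests and exact
    branch-and-bound minimum vertex-pair distances, a parametric gantry-head
    and couch model posed in the fixed DICOM patient frame, extremal-coordinate
    auto-registration of add-on body and couch structures, arc sampling with
    safety-margin risk classification and maximum gantry-range search, ROC
    validation of safety margins against (simulated) physical clearance
    measurements, and synthetic calibration and anthropomorphic phantom
    generators so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
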