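Package: kinscore
Title: Clinical Score Estimation from Upper-Limb Kinematics in
    Rehabilitation Gaming Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates upper-extremity clinical scores (Fugl-Meyer upper
    extremity, Chedoke Arm and Hand Activity Inventory, Barthel Index)
    from hand trajectories recorded during unsupervised rehabilitation
    gaming sessions.  Implements timescale-resolved kinematic
    descriptors based on Gaussian trajectory smoothing (Smoothness and
    the Total Goal-Directed Movement, TGDM), a bounded "double-noise"
    tanh regression model fitted by maximum a posteriori inference with
    Gauss-Hermite quadrature, and a clinimetric evaluation layer
    (repeated cross-validation, intraclass correlation, minimal
    detectable change, recovery sensitivity).  A session simulator with
    adaptive task difficulty generates synthetic cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    pracma,
    signal,
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
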