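Package: hoverstab
Title: Stability Mechanics and Energetics of Hovering in Near-Neutrally
    Buoyant Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the biomechanics and metabolic cost of
    hovering in near-neutrally buoyant fishes. Provides a rigid-body
    torque-balance simulator of postural stabilization driven by the
    separation between the centers of mass and buoyancy, intermittent-flow
    respirometry estimation of oxygen consumption rates, posture and fin
    kinematics from 3D landmark trajectories, morphometric computation of
    center-of-mass and center-of-buoyancy geometry, multilinear
    morphology-to-metabolism regression with drop and permutation variable
    importance, topology-based (Abouheif) phylogenetic-signal tests, and a
    synthetic-data generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
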