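Package: xptflow
Title: Intraoral Waterflow Analysis for Suction Feeding from X-Ray Particle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo intraoral waterflow during suction
    feeding in fish, from biplanar X-ray marker and tracer trajectories
    (XMALab-style 3D point exports) to cranium-bound anatomical-frame
    kinematics. Provides rigid-body (Kabsch) pose fitting and anatomical
    coordinate systems, automatic segmentation of feeding sequences into
    approach, intake, stasis, reverse-flow and backflow phases from water
    tracer velocities, Menger path-curvature statistics separating water from
    food trajectories, skeletal kinematic traces (gape, hyoid depression,
    opercula abduction) with peak-sequence classification, Stokes-law tracer
    density estimation from drop tests, a reduced-order suction-flow particle
    advection model for tracer fidelity assessment, and a seeded synthetic
    feeding-sequence generator providing ground truth for every stage.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
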