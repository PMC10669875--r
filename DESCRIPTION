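Package: crosshairsim
Title: Laser Crosshair Simulator Registration for Mixed-Reality Neuronavigation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hardware-free geometric framework for registration of
    mixed-reality neuronavigation holograms via a laser crosshair
    simulator.  Provides proper rigid transforms between the named
    coordinate frames of the scanner/simulator/virtual-space chain,
    scan-geometry handling and scanner reference-line marking on
    triangulated head surfaces, the three-orthogonal-plane laser rig
    with plane-mesh crosshair projection, calibration-sphere intrinsic
    and extrinsic calibration, 6-DOF simulator deployment by curve
    matching, and a target registration error (TRE) evaluation protocol
    with least-squares rigid extrapolation and one-way ANOVA summaries.
    A seeded synthetic head-phantom generator makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
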