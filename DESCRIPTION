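Package: dynland
Title: Dynamic Landscapes of Molecular Reorientational Motion from NMR
    Relaxation and Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to construct site- and timescale-resolved maps of
    molecular reorientational motion ("dynamic landscapes") by combining
    solid-state NMR relaxation data with molecular dynamics trajectories.
    Implements rank-2 reorientational correlation functions, a frame-based
    separation of bond motion into independent components with residual
    tensor bookkeeping, timescale-selective detector analysis of relaxation
    rates and trajectory correlation functions, and fitting and combination
    of parameterized correlation-time distributions. Includes a kinematic
    simulator of bond-vector trajectories with analytically solvable
    correlation functions for validation, a CHARMM36 POPC selection preset,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    quadprog,
    minpack.lm,
    bio3d,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
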