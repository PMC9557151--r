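Package: strandmech
Title: Mechanics of Tight-Junction Claudin Strands from Simulation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the lateral mechanics of claudin
    tight-junction strands in membranes. Estimates the two-dimensional
    worm-like-chain persistence length of a strand from tangent-angle
    correlations of its tetramer-center trace, local curvature from
    sliding-window least-squares circle fits, transmembrane-helix tilt and
    bend (kink) angles from Calpha geometry, optimal-superposition backbone
    RMSD, and residue-interface contact distances and occupancies. Includes
    synthetic generators (worm-like chains, kinked helices, contact
    time-series, toy strand structures) with known ground truth so that every
    stage of the pipeline is verifiable without microsecond molecular-dynamics
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
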