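Package: cctraj
Title: Cell Cycle Trajectories as Piecewise-Linear Switching Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the progression of single proliferating cells through the
    cell cycle as a sequence of switches. Provides a deterministic hybrid
    automaton with linear growth in log coordinates, hyperplane-triggered
    state switches and division translations, together with a convex-cone
    feasibility test linking the number of intrinsic states to the trajectory
    dimensionality; an analytically solvable two-variable kinetic model with
    piecewise-constant synthesis and degradation rates, fitted to observed
    trajectory turning points; a single-cell RNA-seq processing pipeline
    (neighbour pooling, trajectory-based library-size normalization,
    elastic principal curves, pseudotime, curvature-based epoch segmentation,
    phase scores, effective rank); doubling-time prediction from the length
    of the principal circle in the phase-score plane; and a synthetic count
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
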