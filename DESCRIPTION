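Package: selfavoid
Title: Self-Avoidance Simulation and Morphometrics for Branching Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based lattice simulation of epithelial branching
    morphogenesis patterned by self-avoidance: growing tubule trees secrete a
    repulsive factor whose concentration decays exponentially with distance,
    and tips branch, steer and slow in response to the summed field. The
    package reproduces the emergent narrowing of divergence angles (a wide
    first branch followed by narrower later branches) and collision avoidance
    between neighbouring trees, and ships the accompanying morphometric
    toolkit (divergence angles by branch generation, collision scoring, bead
    closest-approach, tip-speed and closing-speed kinematics) together with
    the categorical statistics used to score such cultures (proportion
    confidence intervals with a continuity term, two-sample z and t tests,
    simple linear regression). Synthetic fixture generators with known ground
    truth make every analysis operation testable without external data.
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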