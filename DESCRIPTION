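Package: prionfoci
Title: Trajectory Kinematics and Geometry of Newly Formed Prion Foci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for 3D single-particle trajectories of newly
    formed Sup35NM prion foci in yeast. Reads manually tracked per-frame
    coordinate tables, computes displacement and speed kinematics with
    rolling (simple moving average) smoothing and linear speed trends, fits
    a correlated-random-walk (Markov) movement model yielding a directional
    correlation coefficient, mean turn angle, and random-walk displacement
    scale, maps aggregate positions onto a conceptual cell sphere as
    relative periphery distances, computes ellipsoid volumes and
    volume-ratio regressions, and estimates prion induction frequencies
    from colony counts. A built-in simulator generates confined correlated
    random walks, noisy membrane edge points, peripherally biased aggregate
    positions, and binomial colony counts with known ground truth for
    parameter-recovery validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
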