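Package: mabpr
Title: Mollified Adaptive Biasing Potential Sampling with Overfill Protection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grid-based mollified adaptive biasing potential (mABP) enhanced
    sampling for low-dimensional collective variables, with overfill
    protection (a fill-limit cap on the deposited bias), collective variables
    for ligand binding (RMS distance to dynamically updated receptor
    reference points, torsion angles), flat-bottom cylindrical and
    CV-cap restraints, seeded BAOAB Langevin dynamics on analytic toy
    systems, free-energy-landscape estimation and replicate averaging,
    basin detection and Boltzmann basin occupancy, DBSCAN pose clustering,
    hysteresis-based binding/unbinding event counting, and fill-limit
    calibration scans. Includes deterministic fixture generators and a
    command-line entry point covering the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
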