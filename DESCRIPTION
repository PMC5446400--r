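Package: dldcluster
Title: Two-Stage Deterministic Lateral Displacement Design and Simulation
    for Tumor Cell Cluster Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design arithmetic, unit-cell viscous flow solves, rigid-cluster
    transport simulation, fluorescence-image cluster enumeration and capture
    statistics for two-stage deterministic lateral displacement (DLD) devices
    that isolate circulating tumor cell (CTC) clusters from blood by size and
    asymmetry. Includes critical-diameter estimators (plug, parabolic-flux,
    Davis, and streamline-based), hydraulic resistance network solving for
    outlet split design, a periodic unit-cell Stokes-Brinkman solver with
    depth correction and wall-shear maps, a kinematic simulator of spheres
    and rigid multi-sphere clusters through tilted pillar arrays, a seeded
    synthetic data generator (cluster populations, fluorescence frames with
    ground truth, count tables), and the image-based single/small/large
    cluster classification and recovery statistics used to characterize
    device performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
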