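Package: motorforge
Title: Optical-Trap, Single-Molecule Motility, and MD Trajectory Analysis
    for Microtubule Motors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of microtubule motor mechanics from three
    classes of raw data: bead-force time series from fixed optical traps
    (trap-stiffness calibration by Lorentzian power-spectrum fits, stall
    detection with last-20% stall forces and 80%-dwell stall times,
    force-probability histograms with Gaussian-mixture fits and unbound-peak
    subtraction, double-exponential stall-time survival fits, and
    median-filtered force-velocity curves in fixed 1-pN bins);
    single-particle TIRF kymograph tracks (processive/static/diffusive
    classification, segment velocities, run lengths); and molecular-dynamics
    trajectories of the dynein microtubule-binding domain on tubulin
    (microtubule-referenced principal axes, signed MTBD and stalk angles,
    angular histogram fits, per-residue RMSF, and salt-bridge, hydrogen-bond
    and hydrophobic contact occupancy). A synthetic-data module generates
    every input class with programmed ground truth (Langevin bead dynamics
    in a harmonic trap with a linear force-velocity motor, drift/diffusion
    tracks, and rigid-body rotation trajectories), so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    bio3d,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
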