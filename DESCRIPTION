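Package: qcmr
Title: Simulation and Motion-Compensated Reconstruction for Free-Breathing
    3D Joint T1/T1rho/T2 Cardiac Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation and reconstruction toolkit for a
    free-breathing, magnetization-prepared 3D joint T1/T1rho/T2 mapping
    sequence with two-point Dixon water/fat encoding. Provides a Bloch
    simulator of the 5-heartbeat preparation schedule (inversion recovery,
    no preparation, spin-lock, T2 preparation, no preparation) and
    dictionary generation; digital vial phantoms with coil sensitivities,
    respiratory motion and complex noise; a variable-density Cartesian
    trajectory with spiral profile order and golden-angle increments;
    image-navigator motion estimation, respiratory binning and non-rigid
    motion-compensated encoding; patch-based higher-order low-rank (ADMM)
    reconstruction; two-point Dixon water/fat separation; and voxelwise
    parameter estimation by dictionary matching, plus the spin-echo
    reference fitting models used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
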