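Package: fieldlab
Title: Volume-Conductor Forward Modeling of Transcranial Direct Current Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modeling of the electric field induced in the head by
    transcranial direct current stimulation (tDCS). Generates labeled
    multi-layer sphere head phantoms with geometric region-of-interest
    stand-ins, places sponge-pad and high-definition disk electrodes at
    10-10/10-20 EEG positions, solves the quasi-static continuity equation
    div(sigma grad V) = 0 on the voxel grid with a finite-volume
    discretization and conjugate-gradient solver, derives electric field and
    current density, and compares montages by regional peaks and focality.
    An analytic multi-layer-sphere Legendre-series solution serves as a
    numerical oracle for the voxel solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
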