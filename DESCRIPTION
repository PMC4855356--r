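Package: grnncorr
Title: Delta-Learning Correction of DFT Non-Covalent Interaction Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learned correction of density-functional-theory (DFT)
    non-covalent interaction (NCI) energies toward coupled-cluster quality
    reference values. A general regression neural network (GRNN, a Gaussian
    kernel regression with a single smoothing factor) is trained on molecular
    descriptor tables whose primary descriptor is the DFT-calculated NCI.
    The pipeline partitions samples with the SPXY joint X-Y distance
    algorithm (a Kennard-Stone variant), screens descriptors by partial
    least squares coefficient magnitude, selects the final input subset by
    cross-validated RMSE, optimises the smoothing factor on a grid, and
    reports OECD-style validation statistics (RMSE, MAE, R-squared, q2,
    cross-validated q2, over-fit flag). A synthetic benchmark generator
    emulating the class structure of the S22/S66/X40 interaction-energy
    databases makes every stage testable without quantum-chemistry runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
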