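Package: surfdelta
Title: Scoring Protein Surface Electrostatic Changes of Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how missense variants change the electrostatic
    character of a protein's molecular surface. Builds a solvent-excluded
    surface on a regular grid, attaches per-vertex electrostatic potential
    (built-in screened-Coulomb model or imported APBS OpenDX grids), selects
    the local surface patch around a mutated site, and compares wild-type
    versus variant potential distributions with a resampling procedure based
    on Welch's t, Kolmogorov-Smirnov, and two-sample Anderson-Darling tests,
    reporting median potential shifts in kBT/ec together with per-test
    p-values. Supports both static structures and pooled conformational
    ensembles (multi-model PDB trajectories).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
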