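Package: boddr
Title: Bond-Oriented Deformation Density Refinement for Small-Molecule Crystallography
Version: 0.1.0
Authors@R: person("boddr", "developers", role = c("aut", "cre"),
    email = "boddr@example.org")
Description: Aspherical scattering factors built from Gaussian deformation
    functions layered on the independent atom model (IAM): BEDE bond-density
    and LONE lone-pair instructions, automatic graph-based assignment of
    database parameters, weighted least-squares refinement against
    intensities with global asphericity scale factors, cross-validated
    R_complete and bias statistics, and residual/deformation density maps.
    Reads and writes SHELX INS/RES and HKLF 4 reflection files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
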