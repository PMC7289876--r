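Package: voxdose
Title: Individualized CT Dosimetry and Cancer Risk from Voxel Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Patient-individual radiation dosimetry for helical computed
    tomography. Builds synthetic voxel phantoms with segmented radiosensitive
    organs, runs a simplified Monte Carlo photon transport (photoelectric
    absorption plus Klein-Nishina Compton scatter, kerma approximation) to
    obtain per-voxel relative dose, scales to absorbed dose by free-in-air
    air kerma, aggregates to absorbed, equivalent and effective organ doses
    with ICRP 103 tissue weighting, and converts effective dose to lifetime
    attributable risk (LAR) and excess relative risk (ERR) of cancer
    mortality via BEIR VII age- and sex-interpolated coefficients. Includes
    the conventional dose-length-product conversion method, per-patient
    conversion factors, and cohort-level agreement statistics (Bland-Altman,
    tie-corrected Spearman rank correlation, matched-pair comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
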