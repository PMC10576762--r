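Package: coroflow
Title: Patient-Specific Lumped-Parameter Modelling of Coronary Blood Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and solves patient-specific zero-dimensional
    (electrical-analog) models of the aortic root and coronary arteries to
    estimate absolute coronary blood flow at rest and during hyperemia in
    patients with an anomalous aortic origin of a coronary artery (AAOCA).
    Vessel segments become RLC compartments, the aorta terminates in a
    three-element Windkessel, and each coronary terminates in a six-element
    outlet with an intramyocardial pressure source; total outlet resistances
    are taken from invasive thermodilution measurements. Includes the
    agreement statistics used to validate such models against in-vivo flow
    (exact Wilcoxon signed-rank, Spearman correlation, Bland-Altman limits
    of agreement, flow splits), a Monte-Carlo uncertainty-quantification
    experiment over coronary resistances, a synthetic-cohort generator, and
    a packaged 19-patient validation cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
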