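Package: ddmqa
Title: Dose-Difference-Minimum and Gamma Analysis for Planar Dose QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of scanned-beam
    radiotherapy. Compares a measured planar dose distribution (e.g. from an
    ion-chamber array) against a treatment-planning-system calculation using
    both the classical gamma index and the dose-difference-minimum (DDM)
    metric, which reports the signed minimum dose deviation over all
    calculated test points within a fixed, empirically derived search radius.
    Includes tracked two-stage image registration (DFT coarse alignment plus
    least-squares refinement), beamlet spot-accuracy statistics for deriving
    the search radius, acceptance-region area (AUC) geometry, a synthetic
    plane generator with controlled error structure, deviation histograms and
    heat-map reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
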