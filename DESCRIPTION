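Package: echoasd
Title: Virtual 3D Echocardiographic Measurement of Atrial Septal Defects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates rotational-probe (TTO) and full-volume 3D
    echocardiographic acquisitions of digital heart phantoms with a
    parameterized atrial septal defect, reconstructs Cartesian volumes by
    polar-to-Cartesian scan conversion, despeckles them with a multiscale
    median-term anisotropic diffusion filter, segments myocardium from the
    cardiac cavity with fuzzy c-means initialized level sets evolved without
    reinitialization, extracts the defect rim, and measures its long
    diameter, short diameter and area in physical units. Includes the
    validation statistics used to compare virtual against ground-truth
    measurements (Pearson r with its significance value), a phantom
    replication study, and a naive Bayes classifier with genetic-algorithm
    feature selection for tabular diagnosis records.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
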