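Package: lungcad
Title: Pulmonary Nodule Computer-Aided Detection for Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A computer-aided-detection (CAD) pipeline for pulmonary nodules
    in chest CT: lung-field segmentation by iterative optimal (isodata)
    thresholding and 3D region connectivity, per-slice cavity filling and
    morphological contour repair to recover dense and juxtapleural
    structures, a variable-radius ring (annulus-contrast) filter for
    suspected-shadow detection, shape and intensity feature extraction with
    rule-based or linear-discriminant candidate screening, and FROC-style
    sensitivity / false-positive evaluation. Includes a synthetic thoracic
    CT phantom generator with known lung and nodule ground truth so every
    stage is testable without patient data, plus readers and writers for
    DICOM series, NIfTI and MetaImage volumes, and CSV candidate lists.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
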