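Package: perirad
Title: Peritumoral DCE-MRI Radiomics with PLS Classification
Version: 0.1.0
Authors@R: person("perirad", "developers", role = c("aut", "cre"),
    email = "perirad@example.org")
Description: A tested pipeline for predicting high recurrence-risk class
    (Oncotype DX recurrence score > 25) from dynamic contrast-enhanced
    breast MRI radiomics. Builds 4-mm peritumoral ring masks by
    physical-unit morphological dilation and erosion, extracts a
    multi-filter, multi-resolution radiomics feature battery (first-order,
    shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM) from tumor and peritumoral
    compartments on two DCE phases, selects inter-reader repeatable
    features (r > 0.95), classifies with partial least squares under
    leave-one-out nested cross-validation, and assesses significance with
    a permutation-null AUC test. Ships a synthetic 3D phantom cohort
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
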