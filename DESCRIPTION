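Package: svxresp
Title: Supervoxel-Level Spatial Response Assessment in Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spatially resolved discrimination of true tumor progression from
    pseudoprogression in glioblastoma using multimodal imaging. Implements a
    complete supervoxel-level analysis pipeline: leakage-corrected cerebral
    blood volume from dynamic susceptibility contrast (DSC) MRI, white-matter
    referenced tumor-to-background normalization of amino-acid (FET) PET,
    voxel-wise response labeling of the contrast-enhancing tumor from a
    registered follow-up scan, masked 3D SLIC supervoxel clustering of the
    multi-channel input, IBSI-style first-order and gray-level co-occurrence
    matrix radiomics, and a patient-grouped cross-validated random forest
    classifier with impurity-based feature importances. A multimodal digital
    phantom generator with planted progression/pseudoprogression geography
    provides ground truth for end-to-end validation without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    rpart,
    pROC,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
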