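Package: lsccframe
Title: Landmark-Based Coordinate System for Temporal-Bone CT and MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs an anatomical coordinate system for temporal-bone
    CT and MR volumes from four landmarks on the lateral semicircular
    canals (LSCC): a total-least-squares plane is fitted to the landmarks,
    a right-handed frame is built from their projections, and the
    resulting rigid transform places any image or point set in a common,
    patient- and modality-independent reference. Transforming CT and MR
    volumes of the same subject into this frame co-registers them without
    external fiducials. The package also provides the accompanying
    evaluation suite (two-way random-effects intraclass correlation with
    absolute agreement, intra- and inter-rater difference summaries,
    target registration error on held-out landmarks, Bland-Altman
    agreement analysis, and a planarity check of the canal landmarks)
    together with a synthetic landmark/phantom generator so the whole
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    png,
    readxl,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
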