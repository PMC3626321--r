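Package: aortacad
Title: Computer-Aided Detection of Aortic Dissection and Penetrating
    Aortic Ulcer in Contrast-Enhanced CT
Version: 0.1.0
Authors@R:
    person("aortacad", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A computer-aided diagnosis (CAD) pipeline for axial
    contrast-enhanced CT of the thoracic aorta. The contrast-filled
    aortic lumen is segmented by Hounsfield-unit (HU) range thresholding
    and connected-component labeling, tracked slice to slice from seed
    positions, and each aortic cross-section is classified as circle-like
    (healthy) or a dissection candidate by a gradient-pair circle
    detection test built on the Sobel operator. Penetrating aortic ulcer
    (PAU) candidates are detected as hyperintense connected components
    inside the aortic boundary. A synthetic phantom generator with ground
    truth makes every stage testable without patient data, and an
    evaluation module tallies per-object sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
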