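Package: igrtmotion
Title: Setup-Error, Margin and Dose-Impact Analysis for Image-Guided
    Prostate Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inter- and intrafractional target motion in
    image-guided radiotherapy of prostate cancer and to propagate it into
    treatment margins and dose. The package segments an endorectal balloon
    (ERB) and implanted fiducial markers (FM) from CT/CBCT-like volumes,
    selects a per-patient reference scan from FM/ERB centroid distances,
    decomposes per-fraction displacements into group mean, systematic and
    random components, computes CTV-to-PTV margins with the Stroom
    (2.0*Sigma + 0.7*sigma) and van Herk (2.5*Sigma + 0.7*sigma) recipes,
    accumulates isocenter-shifted dose into structure DVHs with a paired
    signed-rank comparison, and applies an offline adaptive-replanning
    decision rule based on the first treatment fractions. A digital phantom
    generator produces cohorts with known ground-truth motion so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
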