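Package: dorsalcode
Title: Quantification of Multiplex FISH Neuropeptide Expression in the
    Spinal Dorsal Horn
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for quantifying multiplex single-molecule
    fluorescence in situ hybridization (RNAscope-style) images of spinal
    dorsal horn sections: nucleus and soma segmentation, probe spot
    detection, spot-to-cell assignment, negative-control-calibrated
    positivity calling, neuropeptide co-expression matrices and laminar
    distribution of expressing cells, together with the count-level
    filtering and congruence logic used for translatome (TRAP-seq)
    enrichment screens.  A synthetic dorsal-horn tissue simulator with
    full ground truth makes every stage testable without any imaging
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    MASS,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
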