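Package: evcounter
Title: Enumeration of Leukocyte-Derived Extracellular Vesicles and Blood
    Cells in Multichannel Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and enumerates leukocytes, large leukocyte-derived
    extracellular vesicles (ldEVs), platelets and red blood cells in
    multichannel immunofluorescence images of diluted whole blood or of
    EpCAM-enriched samples.  Objects are segmented by thresholding above
    the local background, measured (morphology plus per-channel intensity
    statistics) and classified with declarative linear gate libraries on
    nuclear dye, CD45, CD61 and CD235a signals.  Per-well class counts are
    extrapolated to blood volume, summarised over technical replicates and
    compared against reference hematology counts.  A synthetic blood-image
    generator with a known ground truth (Poisson well loading, disc
    rendering with defocus blur, per-marker expression levels) makes the
    whole pipeline testable end to end without any external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
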