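Package: lfaquant
Title: Quantification of Duplex Fluorescence Lateral Flow Assays with
    Hook-Effect Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for quantitative readout of duplex fluorescence lateral
    flow assays (LFA) measuring procalcitonin (PCT) and C-reactive protein
    (CRP) in serum. Simulates strip images from forward signal models,
    extracts test-line peak areas by profile densitometry with Simpson's
    3/8 integration, fits linear and Akima-spline calibration curves,
    inverts the non-monotone (high-dose hook) CRP curve, and resolves the
    resulting two-candidate ambiguity with a 1:10 serial-dilution
    consistency check. Includes the validation machinery used to assess
    such platforms: triplicate summaries, calibrator selection,
    method-comparison statistics, and sepsis staging by PCT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
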