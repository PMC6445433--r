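Package: octaq
Title: Vessel Density, Flow Index and Case-Control Statistics for En Face
    OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies en face optical coherence tomography angiography
    (OCTA) scans of the macula and optic disc: Phansalkar local and Shanbhag
    global binarization, foveal-avascular-zone background thresholding,
    vessel density, microcapillary vessel density after large-vessel
    masking, skeleton-based vessel length density, and the adjusted flow
    index, over physically calibrated annular regions of interest. Includes
    the matched case-control statistical battery (normality-gated Student
    t / Mann-Whitney comparisons, Hedges g, Pearson/Spearman correlations
    against cognitive scores, two-way single-measure intraclass
    correlations) and a synthetic angiogram/cohort generator with known
    ground truth so the full pipeline is testable without patient imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
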