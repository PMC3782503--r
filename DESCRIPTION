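Package: invadoquant
Title: Quantification of Invadopodia-Driven Matrix Degradation and
    Intensity-Correlation Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify focal extracellular-matrix proteolysis by
    invadopodia in fluorescence in situ zymography images and to assess
    the co-dependence of two fluorescence channels with Li's intensity
    correlation analysis (per-pixel product of the differences from the
    mean, the intensity correlation quotient and its sign-test
    significance, and threshold/ratio colocalization masks). Includes the
    Invadopodia Index (percentage of proteolytically active,
    actin/cortactin-positive cells times the mean number of active spots
    per cell), immunohistochemistry positivity scoring with binomial
    summaries, Table-style contingency breakdowns with nonparametric
    association tests, Nottingham Prognostic Index grouping, seeded
    synthetic generators for two-channel stacks, digestion scenes and
    patient cohorts, and TIFF/CSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
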