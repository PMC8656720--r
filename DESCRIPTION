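Package: mftme
Title: Cell Identification and Tumor-Microenvironment Vicinity Analysis for
    Multiplexed Immunofluorescence of Mycosis Fungoides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses multispectral immunofluorescence fields of
    cutaneous T-cell lymphoma lesions. Cells are detected per marker channel by
    Bradley locally adaptive thresholding, artifact filtering and seeded
    watershed instance splitting; marker co-staining is called by an 80
    percent bounding-box overlap rule against DAPI nuclear anchors; phenotypes
    (malignant CD3+CD4+TOX+, exhausted BTLA+CD4+, effector CD4+, CD8+ T, NK)
    are assigned by prioritized marker rules; infiltrate densities are
    quantified inside the 75 micrometre vicinity of malignant cells; and group
    differences are tested with Welch t-tests and one-way ANOVA with
    Sidak-Holm correction. A synthetic-field generator plants ground-truth
    cell tables at stage- and response-specific densities so every stage of
    the pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
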