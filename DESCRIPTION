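Package: abtsscreen
Title: Colony-Overlay Densitometry and ABTS Kinetics for Secreted-Enzyme Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for high-throughput colorimetric screens of
    secreted enzyme activity on colony arrays. Converts plate images of 384-colony
    arrays assayed with an ABTS overlay into background-corrected per-site
    densitometry, applies plate-median normalization, concentric-rectangle zone
    correction for edge artifacts, robust modified Z-scores (MAD-based), and
    replicate-supported hit calling. A companion module quantifies liquid ABTS
    kinetic assays: linear-range trimming of absorbance traces, Beer-Lambert
    conversion to enzymatic activity, OD600 normalization, fold change versus a
    reference strain, and one-way ANOVA with Dunnett or Tukey multiple-comparison
    correction. A synthetic-data module generates plate images, blank plates,
    kinetic traces and activity tables with known ground truth so the whole
    pipeline is testable without raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    yaml,
    EBImage,
    multcomp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
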