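Package: embryoquant
Title: Quantification of Mitotic Chromosome Dynamics in One-Cell Embryo
    Time-Lapse Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable implementations of the fluorescence quantification
    procedures used in live imaging of one-cell C. elegans embryos:
    maximum/sum z-projections and ROI intensity measurement on multi-page
    TIFF time series, histogram auto-thresholding (Otsu and maximum
    entropy), ring-background-corrected metaphase-plate intensities, the
    chromosome condensation parameter with NEB-aligned time courses and
    loess smoothing, total nuclear intensity time courses, spindle
    pole-to-pole distances, NEB-to-anaphase timing, FRAP line profiles,
    embryonic lethality, and a statistical decision tree (Shapiro-Wilk
    gated Student/Welch t tests, ANOVA with Tukey-Kramer, Kruskal-Wallis
    with Dunn and Benjamini-Hochberg). Includes seedable synthetic-image
    and measurement generators with recorded ground truth so every stage
    is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
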