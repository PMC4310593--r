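Package: ectishape
Title: Shape Analysis of the Epithelial-Connective Tissue Interface in
    Nonlinear Optical Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts the epithelial-connective tissue interface (ECTI) from
    second-harmonic-generation (SHG) microscopy cross-sections and quantifies
    its deviation from linearity, the dimensionless (arc - chord)/chord
    statistic that separates dysplastic from normal oral mucosa. Provides the
    full measurement chain (thresholding, Canny-style edge detection,
    minimal-cost boundary tracing, arc-length geometry), layer and cell
    morphometry (epithelial thickness, nuclear density by multi-scale blob
    detection), cohort statistics (one-way ANOVA with Tukey post hoc
    comparisons, empirical ROC curves with Youden operating points), and a
    synthetic phantom and cohort generator with analytic ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
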