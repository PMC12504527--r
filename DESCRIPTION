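Package: phagoquant
Title: Quantification of Macrophage Bead Engulfment and 3D Marker Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image quantification for fluorescence microscopy assays of
    myeloid cells in brain tissue. Implements 2D phagocytosis scoring of
    bead-engulfing macrophages (maximum intensity projection, per-channel
    percentile normalization, deterministic 2-class K-means segmentation,
    digitization-corrected circularity and size filtering, cell-bead mask
    intersection, per-animal aggregation) and 3D marker colocalization
    (per-object volume and overlapped volume ratios against DAPI, Iba1 and
    P2ry12 masks with hierarchical marker gating). Includes the matching
    statistical toolbox (two-way repeated-measures ANOVA with
    Greenhouse-Geisser correction and Sidak comparisons, one-way ANOVA with
    Tukey HSD, Student and Welch t-tests, Holm adjustment, ROUT outlier
    detection) and a synthetic phantom generator with exact ground truth so
    the full pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    withr,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
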