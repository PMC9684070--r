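Package: ecrestore
Title: Organ-Specific Endothelial Transcriptome Changes Under Obesity and
    Diet Reversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying organ- and subtype-specific
    endothelial cell (EC) transcriptome changes in obesity and after diet
    reversion from single-cell RNA-seq count matrices. Covers cell and gene
    quality control, library-size log-normalization, marker-panel EC subtype
    annotation, per-gene Wilcoxon rank-sum differential expression with
    Benjamini-Hochberg correction and natural-log fold changes,
    downsampling-equalized DEG counting, chow-standardized restoration
    classification under a reversion diet, cross-organ fold-change
    concordance and consistency ranking, EC population-shift quantification,
    platelet-positive EC detection, and integration of GWAS-catalog risk
    genes with mouse DEGs. Ships a negative-binomial single-cell simulator
    with planted, recoverable effect structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
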