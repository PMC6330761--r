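Package: bcl2panel
Title: BCL2-Family Expression Profiling and Venetoclax Sensitivity Ratio
    Across Mature B-Cell Malignancies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for cross-entity analysis of BCL2-family gene
    expression in mature B-cell malignancies on pooled microarray
    cohorts: a synthetic-data generator emulating a multi-series
    patient corpus with matched cell-line RNA-seq, quantile
    normalization with outlier removal and anchoring-gene quality
    control, RNA-seq-guided probe-to-gene selection, nonparametric
    differential profiling (Wilcoxon-Mann-Whitney, Kruskal-Wallis,
    Fisher), PCA factor maps with barycenter confidence ellipses,
    random-forest entity classification for histologic-transformation
    scoring, and a candidate-ratio search relating BCL2-family
    expression ratios such as (BCL2+BCL2L11+BAX)/BCL2L1 to
    venetoclax-monotherapy overall response rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    limma,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
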