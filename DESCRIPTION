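Package: mirnorm
Title: Reference-Gene Stability and Biomarker Evaluation for Serum miRNA qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for circulating-miRNA qPCR studies: sample-level quality
    control (hemolysis index, spike-in consistency), candidate reference-gene
    screening from expression matrices, reference-gene stability ranking by
    the geNorm pairwise-variation and NormFinder variance-decomposition
    algorithms with a comprehensive aggregate ranking, relative
    quantification by the 2^-ddCt method, and diagnostic evaluation of
    biomarkers by ROC analysis (DeLong confidence intervals, Youden-optimal
    cutoffs) and covariate-adjusted partial correlation. Includes a
    synthetic-data generator reproducing the statistical structure of serum
    qPCR studies (per-sample load shifts, gene-specific noise, group
    effects, hemolysis contamination, spike-in controls) and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
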