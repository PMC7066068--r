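Package: mrmrIFS
Title: Mutual-Information mRMR Ranking and Incremental Feature Selection
    for Single-Cell Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers compact gene biomarker panels that discriminate two
    cell populations (e.g. tumor-core versus periphery cells in single-cell
    RNA-seq) by ranking genes with the minimum-redundancy maximum-relevance
    (mRMR) criterion on plug-in mutual information over discretized
    expression, evaluating nested top-k gene sets with a cross-validated
    support vector machine, and selecting the panel size that maximizes the
    Matthews correlation coefficient. Includes confusion-matrix metrics,
    hypergeometric gene-set overlap tests on GMT files, expression matrix
    input/output (dense TSV/CSV and Matrix Market triplets), and a seeded
    negative-binomial-with-dropout synthetic data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    e1071,
    graphics,
    grDevices,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
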