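Package: lungCADx
Title: Wavelet-Domain GLCM Texture Classification of Lung Nodules on CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis (CADx) pipeline that classifies
    thoracic CT slices as containing a cancerous lung nodule or not. Slices
    are standardized by detecting the body circumference with a circular
    Hough transform and masking everything outside it, decomposed with
    Daubechies (db1/db2/db4) orthonormal wavelets at one or two levels, and
    described by 19 gray-level co-occurrence matrix (GLCM) texture features
    per sub-band at four displacement angles. Correlation-based feature
    subset selection with best-first and greedy-forward search reduces the
    descriptor, an exhaustive feature-pair search feeds a radial-basis-
    function support vector machine, and slice decisions are aggregated to
    scan level. Includes a synthetic CT phantom generator with ground truth
    so the whole pipeline is testable without any external dataset, plus
    contingency-table metrics and ROC/AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
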